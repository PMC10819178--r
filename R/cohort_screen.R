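# Medication-plan screening: pairwise interaction tallies per patient,
# cohort-level prevalence, type frequencies, the medication-count trend and
# the DMD/BTKi switch analysis.

#' Unordered drug pairs of one medication plan
#'
#' All `C(m, 2)` pairs of the plan's predictable drugs. Plans with fewer than
#' two predictable drugs yield no pairs.
#'
#' @param drug_ids Character vector of drug IDs (a set).
#' @param predictable Optional character vector restricting to drugs with
#'   structures; drugs outside it are ignored.
#' @return Tibble with columns `drug_a`, `drug_b` (`drug_a < drug_b`).
#' @export
enumerate_plan_pairs <- function(drug_ids, predictable = NULL) {
  ids <- sort(unique(drug_ids))
  if (!is.null(predictable)) ids <- ids[ids %in% predictable]
  if (length(ids) < 2) {
    return(tibble::tibble(drug_a = character(0), drug_b = character(0)))
  }
  p <- t(utils::combn(ids, 2))
  tibble::tibble(drug_a = p[, 1], drug_b = p[, 2])
}

#' All unordered drug pairs occurring in a cohort
#'
#' The same pair occurring in several patients is returned once.
#'
#' @param plans Plans tibble from [load_plans()] or [gen_cohort()].
#' @param predictable Optional restriction as in [enumerate_plan_pairs()].
#' @return Tibble with `drug_a`, `drug_b`.
#' @export
cohort_pairs <- function(plans, predictable = NULL) {
  all_pairs <- dplyr::bind_rows(lapply(plans$drug_ids, enumerate_plan_pairs,
                                       predictable = predictable))
  dplyr::distinct(all_pairs)
}

#' Screen a cohort's medication plans for interactions
#'
#' Counts, per patient, the `C(m, 2)` pairwise combinations of predictable
#' co-medications ("counting with repetitions" across patients: a pair taken
#' by several patients counts once per patient) and the gold-standard and
#' predicted interactions among them. A pair with two predicted types
#' contributes two DDIs but one combination.
#'
#' @param plans Plans tibble.
#' @param gold Gold-standard tibble.
#' @param predictions A `ddi_predictions` object (or its records tibble).
#' @param registry Drug registry; drugs without structures are excluded from
#'   pair enumeration and plan membership is validated against it.
#' @return A list of class `ddi_cohort_report`: `per_patient` tibble, totals,
#'   prevalences, and per-type frequency tables for both sources.
#' @export
screen_cohort <- function(plans, gold, predictions, registry) {
  records <- if (inherits(predictions, "ddi_predictions")) {
    predictions$records
  } else {
    predictions
  }
  unknown <- setdiff(unlist(plans$drug_ids), registry$drug_id)
  if (length(unknown)) {
    stop("plans reference unknown drug ID(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  predictable <- registry$drug_id[registry$has_structure]
  gold_key <- .pair_key(gold$subject_id, gold$object_id)
  gold_type <- stats::setNames(gold$type_id, gold_key)
  pred_key <- .pair_key(records$subject_id, records$object_id)
  pred_by_key <- split(records$type_id, pred_key)
  per <- lapply(seq_len(nrow(plans)), function(i) {
    pairs <- enumerate_plan_pairs(plans$drug_ids[[i]], predictable)
    keys <- .pair_key(pairs$drug_a, pairs$drug_b)
    g_hit <- keys[keys %in% names(gold_type)]
    p_types <- pred_by_key[keys[keys %in% names(pred_by_key)]]
    tibble::tibble(
      patient_id = plans$patient_id[i],
      course = plans$course[i],
      n_meds = length(plans$drug_ids[[i]]),
      n_predictable = sum(plans$drug_ids[[i]] %in% predictable),
      n_pairs = nrow(pairs),
      gold_ddis = length(g_hit),
      pred_ddis = sum(lengths(p_types)),
      pred_combinations = length(p_types),
      gold_types = list(unname(gold_type[g_hit])),
      pred_types = list(unlist(p_types, use.names = FALSE)))
  })
  per <- dplyr::bind_rows(per)
  type_freq <- function(col) {
    t <- table(factor(unlist(per[[col]]), levels = seq_len(86)))
    tibble::tibble(type_id = as.integer(names(t)), n = as.integer(t))
  }
  structure(list(
    per_patient = per[, c("patient_id", "course", "n_meds", "n_predictable",
                          "n_pairs", "gold_ddis", "pred_ddis",
                          "pred_combinations")],
    total_pairs = sum(per$n_pairs),
    gold_total = sum(per$gold_ddis),
    pred_total = sum(per$pred_ddis),
    pred_combinations = sum(per$pred_combinations),
    prevalence_gold = mean(per$gold_ddis > 0),
    prevalence_pred = mean(per$pred_ddis > 0),
    type_freq_gold = type_freq("gold_types"),
    type_freq_pred = type_freq("pred_types")),
    class = "ddi_cohort_report")
}

#' Fraction of patients at risk of a DDI type after a therapy switch
#'
#' For each patient, all current DMD-category drugs are removed from the
#' plan, the candidate drug is added (idempotently), and the patient counts
#' as at risk iff at least one predicted interaction of `type_id` exists
#' between the candidate and any remaining drug.
#'
#' @param plans Plans tibble.
#' @param candidate_drug Drug ID of the DMD or BTKi candidate (must have a
#'   structure).
#' @param type_id Interaction type of interest.
#' @param predictions `ddi_predictions` covering the candidate's pairs.
#' @param registry Drug registry (supplies the DMD category and structures).
#' @return Fraction of patients in `[0, 1]`.
#' @export
switch_risk <- function(plans, candidate_drug, type_id, predictions,
                        registry) {
  records <- if (inherits(predictions, "ddi_predictions")) {
    predictions$records
  } else {
    predictions
  }
  cand <- registry[registry$drug_id == candidate_drug, ]
  if (nrow(cand) != 1 || !cand$has_structure) {
    stop("candidate drug must be a registry entry with a structure",
         call. = FALSE)
  }
  dmds <- registry$drug_id[registry$category == "dmd"]
  predictable <- registry$drug_id[registry$has_structure]
  rec <- records[records$type_id == type_id, ]
  partner_keys <- .pair_key(rec$subject_id, rec$object_id)
  at_risk <- vapply(plans$drug_ids, function(ids) {
    rest <- setdiff(intersect(ids, predictable), c(dmds, candidate_drug))
    if (length(rest) == 0) return(FALSE)
    any(.pair_key(candidate_drug, rest) %in% partner_keys)
  }, logical(1))
  mean(at_risk)
}

#' Switch-risk matrix over candidates and types
#'
#' @param plans,predictions,registry As in [switch_risk()].
#' @param candidates Candidate drug IDs (DMDs/BTKis).
#' @param type_ids Interaction types of interest.
#' @return Numeric matrix, candidates x types, of patient fractions.
#' @export
switch_risk_matrix <- function(plans, candidates, type_ids, predictions,
                               registry) {
  m <- vapply(type_ids, function(t) {
    vapply(candidates, switch_risk, numeric(1), plans = plans,
           type_id = t, predictions = predictions, registry = registry)
  }, numeric(length(candidates)))
  m <- matrix(m, nrow = length(candidates),
              dimnames = list(candidates, paste0("type_", type_ids)))
  m
}

#' Interaction burden versus medication count
#'
#' Emits the per-patient (medication count, predicted DDI count) table with
#' an exponential trend fitted by log-linear least squares
#' (`log(count + 1) ~ m`) and a bootstrap confidence band.
#'
#' @param report A `ddi_cohort_report`.
#' @param n_boot Bootstrap replicates for the confidence band. Default 200.
#' @param level Confidence level. Default 0.95.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `table` (per-patient `m`, `ddi_count`), `fit`
#'   (intercept/slope on the log scale, or `NULL` if fewer than 3 distinct
#'   medication counts) and `curve` (fitted values with `lo`/`hi` band).
#' @export
ddi_count_vs_medications <- function(report, n_boot = 200L, level = 0.95,
                                     seed = 1L) {
  stopifnot(inherits(report, "ddi_cohort_report"))
  tab <- tibble::tibble(m = report$per_patient$n_meds,
                        ddi_count = report$per_patient$pred_ddis)
  if (length(unique(tab$m)) < 3) {
    warning("fewer than 3 distinct medication counts; trend fit skipped")
    return(list(table = tab, fit = NULL, curve = NULL))
  }
  fit <- stats::lm(log(ddi_count + 1) ~ m, data = tab)
  grid <- tibble::tibble(m = seq(min(tab$m), max(tab$m)))
  boot_pred <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(tab), replace = TRUE)
      bf <- stats::lm(log(ddi_count + 1) ~ m, data = tab[idx, ])
      stats::predict(bf, grid)
    }, numeric(nrow(grid)))
  })
  alpha <- (1 - level) / 2
  curve <- tibble::tibble(
    m = grid$m,
    fit = exp(stats::predict(fit, grid)) - 1,
    lo = exp(apply(boot_pred, 1, stats::quantile, alpha)) - 1,
    hi = exp(apply(boot_pred, 1, stats::quantile, 1 - alpha)) - 1)
  list(table = tab,
       fit = stats::setNames(stats::coef(fit), c("intercept", "slope")),
       curve = curve)
}

#' Export a cohort report
#'
#' Writes the report totals as JSON and the per-type frequency table as CSV.
#'
#' @param report A `ddi_cohort_report`.
#' @param json_path,freq_csv_path Output paths.
#' @return `json_path`, invisibly.
#' @export
export_cohort_report <- function(report, json_path, freq_csv_path) {
  jsonlite::write_json(list(
    total_pairs = report$total_pairs, gold_total = report$gold_total,
    pred_total = report$pred_total,
    pred_combinations = report$pred_combinations,
    prevalence_gold = report$prevalence_gold,
    prevalence_pred = report$prevalence_pred),
    json_path, auto_unbox = TRUE, digits = NA)
  freq <- dplyr::full_join(
    dplyr::rename(report$type_freq_gold, gold_n = "n"),
    dplyr::rename(report$type_freq_pred, pred_n = "n"), by = "type_id")
  readr::write_csv(freq, freq_csv_path)
  invisible(json_path)
}
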