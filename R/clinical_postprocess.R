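# Decision-support analyses: mechanism candidates for adverse-effect DDIs
# (type 26) and critical-DDI-avoiding drug substitution.

.ADVERSE_TYPE <- 26L

#' Mechanism candidates for adverse-effect interactions
#'
#' Finds drug pairs that (1) occur in the cohort, (2) carry a gold-standard
#' interaction of type 26 (increased risk or severity of adverse effects)
#' that is also predicted, and (3) received at least one additional predicted
#' type, which may point to the pharmacokinetic or pharmacodynamic mechanism
#' behind the adverse effect.
#'
#' @param pairs Cohort pair tibble (`drug_a`, `drug_b`), e.g. from
#'   [cohort_pairs()].
#' @param gold Gold-standard tibble.
#' @param predictions `ddi_predictions` object or records tibble.
#' @return Tibble with one row per (pair, mechanism type): `drug_a`,
#'   `drug_b`, `mechanism_type`, `score`, sorted by descending score within
#'   each pair.
#' @export
find_mechanism_candidates <- function(pairs, gold, predictions) {
  records <- if (inherits(predictions, "ddi_predictions")) {
    predictions$records
  } else {
    predictions
  }
  pair_keys <- .pair_key(pairs$drug_a, pairs$drug_b)
  gold26 <- gold[gold$type_id == .ADVERSE_TYPE, ]
  gold26_keys <- .pair_key(gold26$subject_id, gold26$object_id)
  rec <- records[.pair_key(records$subject_id, records$object_id) %in%
                   intersect(pair_keys, gold26_keys), ]
  if (nrow(rec) == 0) {
    return(tibble::tibble(drug_a = character(0), drug_b = character(0),
                          mechanism_type = integer(0), score = numeric(0)))
  }
  rec$key <- .pair_key(rec$subject_id, rec$object_id)
  by_pair <- split(rec, rec$key)
  out <- lapply(by_pair, function(r) {
    if (!any(r$type_id == .ADVERSE_TYPE)) return(NULL)  # type 26 not predicted
    mech <- r[r$type_id != .ADVERSE_TYPE, ]
    if (nrow(mech) == 0) return(NULL)                   # no co-predicted type
    mech <- mech[order(-mech$score, mech$type_id), ]
    tibble::tibble(drug_a = pmin(mech$subject_id, mech$object_id),
                   drug_b = pmax(mech$subject_id, mech$object_id),
                   mechanism_type = mech$type_id, score = mech$score)
  })
  dplyr::bind_rows(out)
}

#' Alternative drugs with identical pharmacology
#'
#' Approved drugs (other than the input) whose target-action set equals the
#' input drug's set; with `superset_match = TRUE`, candidates whose set is a
#' superset also qualify.
#'
#' @param drug_id Drug to replace.
#' @param registry Drug registry.
#' @param superset_match Relax exact set equality to superset matching.
#'   Default `FALSE`.
#' @param require_structure Only return candidates whose structure is
#'   available (needed to evaluate candidate pairs). Default `TRUE`.
#' @return Character vector of candidate drug IDs, sorted.
#' @export
find_alternatives <- function(drug_id, registry, superset_match = FALSE,
                              require_structure = TRUE) {
  row <- registry[registry$drug_id == drug_id, ]
  stopifnot(nrow(row) == 1)
  target_set <- parse_target_sets(row$targets)[[1]]
  if (length(target_set) == 0) {
    warning("drug ", drug_id, " has no target annotations; no alternatives")
    return(character(0))
  }
  cand <- registry[registry$approved & registry$drug_id != drug_id, ]
  if (require_structure) cand <- cand[cand$has_structure, ]
  sets <- parse_target_sets(cand$targets)
  ok <- vapply(sets, function(s) {
    if (superset_match) all(target_set %in% s) else identical(s, target_set)
  }, logical(1))
  sort(cand$drug_id[ok])
}

#' Maximum critical-type activation of a candidate pair
#'
#' Evaluates both orderings of the pair and returns the largest activation
#' over the critical interaction types.
#'
#' @param drug_a,drug_b Drug IDs.
#' @param model,projection,profiles Classifier and features.
#' @param critical Critical type set. Default [critical_types()].
#' @return A number in `[0, 1]`.
#' @export
max_critical_activation <- function(drug_a, drug_b, model, projection,
                                    profiles, critical = critical_types()) {
  P <- pair_activations(c(drug_a, drug_b), c(drug_b, drug_a), model,
                        projection, profiles)
  max(P[, critical])
}

#' Suggest substitutions that avoid critical interactions
#'
#' For a drug pair flagged with a predicted critical interaction, tries to
#' replace either drug by each of its target-matched approved alternatives.
#' A suggestion is accepted iff every critical-type activation of the new
#' pair, in both orderings, is below `safety_threshold`, and (conservative
#' addition) the gold standard contains no critical record for the new pair.
#'
#' @param drug_a,drug_b The flagged pair.
#' @param registry Drug registry.
#' @param model,projection,profiles Classifier and features.
#' @param gold Optional gold standard for the conservative veto.
#' @param safety_threshold Maximum tolerated critical activation. Default
#'   0.47.
#' @param critical Critical type set. Default [critical_types()].
#' @param superset_match Passed to [find_alternatives()].
#' @return Tibble with `replaced`, `alternative`, `partner`,
#'   `max_critical_activation`; zero rows mean the pair is not preventable.
#' @export
suggest_substitutions <- function(drug_a, drug_b, registry, model, projection,
                                  profiles, gold = NULL,
                                  safety_threshold = 0.47,
                                  critical = critical_types(),
                                  superset_match = FALSE) {
  gold_crit_keys <- if (!is.null(gold)) {
    g <- gold[gold$type_id %in% critical, ]
    .pair_key(g$subject_id, g$object_id)
  } else {
    character(0)
  }
  rows <- list()
  for (replaced in c(drug_a, drug_b)) {
    partner <- setdiff(c(drug_a, drug_b), replaced)
    alts <- suppressWarnings(
      find_alternatives(replaced, registry, superset_match = superset_match))
    alts <- setdiff(alts, c(drug_a, drug_b))
    alts <- alts[alts %in% rownames(profiles)]
    for (alt in alts) {
      if (alt == partner) next
      mca <- max_critical_activation(alt, partner, model, projection,
                                     profiles, critical)
      if (mca >= safety_threshold) next
      if (.pair_key(alt, partner) %in% gold_crit_keys) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        replaced = replaced, alternative = alt, partner = partner,
        max_critical_activation = mca)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(replaced = character(0), alternative = character(0),
                          partner = character(0),
                          max_critical_activation = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Substitution analysis over all flagged cohort pairs
#'
#' Applies [suggest_substitutions()] to every cohort pair carrying at least
#' one predicted critical interaction and reports the preventable fraction.
#'
#' @param pairs Cohort pair tibble (`drug_a`, `drug_b`).
#' @param predictions `ddi_predictions` object or records tibble.
#' @inheritParams suggest_substitutions
#' @return List with `flagged` (pair tibble with their critical types),
#'   `suggestions` (tibble, one row per accepted suggestion, with the pair
#'   columns), and `preventable_fraction`.
#' @export
substitution_analysis <- function(pairs, predictions, registry, model,
                                  projection, profiles, gold = NULL,
                                  safety_threshold = 0.47,
                                  critical = critical_types()) {
  records <- if (inherits(predictions, "ddi_predictions")) {
    predictions$records
  } else {
    predictions
  }
  crit <- records[records$type_id %in% critical, ]
  crit_keys <- .pair_key(crit$subject_id, crit$object_id)
  pk <- .pair_key(pairs$drug_a, pairs$drug_b)
  flagged <- pairs[pk %in% crit_keys, , drop = FALSE]
  if (nrow(flagged) == 0) {
    return(list(flagged = flagged, suggestions = NULL,
                preventable_fraction = NA_real_))
  }
  flagged$critical_types <- lapply(.pair_key(flagged$drug_a, flagged$drug_b),
                                   function(k) {
                                     sort(unique(crit$type_id[crit_keys == k]))
                                   })
  sugg <- lapply(seq_len(nrow(flagged)), function(i) {
    s <- suggest_substitutions(flagged$drug_a[i], flagged$drug_b[i], registry,
                               model, projection, profiles, gold = gold,
                               safety_threshold = safety_threshold,
                               critical = critical)
    if (nrow(s) == 0) return(NULL)
    s$drug_a <- flagged$drug_a[i]
    s$drug_b <- flagged$drug_b[i]
    s
  })
  sugg <- dplyr::bind_rows(sugg)
  preventable <- if (nrow(flagged) == 0) NA_real_ else {
    if (is.null(sugg) || nrow(sugg) == 0) 0 else {
      length(unique(.pair_key(sugg$drug_a, sugg$drug_b))) / nrow(flagged)
    }
  }
  list(flagged = flagged, suggestions = sugg,
       preventable_fraction = preventable)
}
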