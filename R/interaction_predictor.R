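# DDI/DFI prediction over compound pairs: activation computation for ordered
# pairs, thresholded typed records, sentence rendering and the structural
# validation of predicted drug-food interactions.

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Output activations for ordered compound pairs
#'
#' Builds the pair feature for every (subject, object) row and runs the
#' classifier, in blocks to bound memory.
#'
#' @param subjects,objects Compound ID vectors of equal length.
#' @param model Trained `ddi_model`.
#' @param projection `ddi_projection`.
#' @param profiles Similarity-profile matrix with compound IDs as row names.
#' @param block Rows per forward block. Default 4000.
#' @return Activation matrix (`length(subjects) x output_dim`).
#' @export
pair_activations <- function(subjects, objects, model, projection, profiles,
                             block = 4000L) {
  stopifnot(length(subjects) == length(objects))
  missing <- setdiff(unique(c(subjects, objects)), rownames(profiles))
  if (length(missing)) {
    stop("no similarity profile for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  red <- project_profiles(projection, profiles)
  rownames(red) <- rownames(profiles)
  n <- length(subjects)
  P <- matrix(NA_real_, n, model$cfg$output_dim)
  starts <- seq(1, n, by = block)
  for (s in starts) {
    i <- s:min(s + block - 1, n)
    X <- cbind(red[subjects[i], , drop = FALSE], red[objects[i], , drop = FALSE])
    P[i, ] <- predict_activations(model, X)
  }
  rownames(P) <- paste(subjects, objects, sep = "\r")
  P
}

# activation matrix -> typed records at a threshold
.records_from_activations <- function(P, subjects, objects, threshold) {
  hits <- which(P >= threshold, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble::tibble(subject_id = character(0), object_id = character(0),
                          type_id = integer(0), score = numeric(0),
                          provenance = character(0)))
  }
  rec <- tibble::tibble(subject_id = subjects[hits[, 1]],
                        object_id = objects[hits[, 1]],
                        type_id = as.integer(hits[, 2]),
                        score = P[hits], provenance = "predicted")
  # if the same type fired in both orderings of a pair, keep the
  # higher-scoring ordering (avoids double counting in tallies)
  rec$key <- .pair_key(rec$subject_id, rec$object_id)
  rec <- rec[order(rec$key, rec$type_id, -rec$score), ]
  rec <- rec[!duplicated(rec[, c("key", "type_id")]), ]
  rec$key <- NULL
  rec[order(rec$subject_id, rec$object_id, rec$type_id), ]
}

#' Predict interactions for all drug pairs
#'
#' Evaluates both orderings of each of the `n (n - 1) / 2` unordered pairs
#' and reports each fired type for the ordering in which it fired (the
#' higher-scoring ordering if both fired).
#'
#' @param drug_ids Compound IDs (at least 2) with profiles available.
#' @param model,projection,profiles See [pair_activations()].
#' @param threshold Activation threshold; the screening default is 0.94.
#' @return A list of class `ddi_predictions` with `records`,
#'   `n_unordered_pairs`, `threshold` and `drug_ids`.
#' @export
predict_all_pairs <- function(drug_ids, model, projection, profiles,
                              threshold = 0.94) {
  drug_ids <- sort(unique(drug_ids))
  stopifnot(length(drug_ids) >= 2)
  pairs <- t(utils::combn(drug_ids, 2))
  subjects <- c(pairs[, 1], pairs[, 2])
  objects <- c(pairs[, 2], pairs[, 1])
  P <- pair_activations(subjects, objects, model, projection, profiles)
  structure(list(records = .records_from_activations(P, subjects, objects,
                                                     threshold),
                 n_unordered_pairs = nrow(pairs), threshold = threshold,
                 drug_ids = drug_ids),
            class = "ddi_predictions")
}

#' Predict drug-food interactions
#'
#' Evaluates both orderings of every food-compound/drug pair with the same
#' 86-type classifier used for drug pairs.
#'
#' @param food_ids,drug_ids Compound ID vectors.
#' @inheritParams predict_all_pairs
#' @return A `ddi_predictions` list with `food_ids` recorded.
#' @export
predict_dfis <- function(food_ids, drug_ids, model, projection, profiles,
                         threshold = 0.94) {
  stopifnot(length(food_ids) >= 1, length(drug_ids) >= 1)
  grid <- expand.grid(f = food_ids, d = drug_ids, stringsAsFactors = FALSE)
  subjects <- c(grid$f, grid$d)
  objects <- c(grid$d, grid$f)
  P <- pair_activations(subjects, objects, model, projection, profiles)
  structure(list(records = .records_from_activations(P, subjects, objects,
                                                     threshold),
                 n_unordered_pairs = nrow(grid), threshold = threshold,
                 drug_ids = sort(unique(drug_ids)),
                 food_ids = sort(unique(food_ids))),
            class = "ddi_predictions")
}

#' Mark predicted records as known or newly predicted
#'
#' A predicted record is known iff the gold standard contains the same
#' unordered pair with the same type.
#'
#' @param records Predicted records tibble.
#' @param gold Gold-standard tibble.
#' @return `records` with a logical `known` column.
#' @export
label_known <- function(records, gold) {
  gold_keys <- paste(.pair_key(gold$subject_id, gold$object_id), gold$type_id)
  records$known <- paste(.pair_key(records$subject_id, records$object_id),
                         records$type_id) %in% gold_keys
  records
}

#' Render interaction records as human-readable sentences
#'
#' Fills the `{subject}` and `{object}` slots of each type's template with
#' the compound names.
#'
#' @param records Tibble with `subject_id`, `object_id`, `type_id`.
#' @param templates Template tibble from [load_templates()].
#' @param names Named character vector mapping compound IDs to display names.
#' @return Character vector of sentences.
#' @export
render_sentences <- function(records, templates, names) {
  missing_tpl <- setdiff(records$type_id, templates$type_id)
  if (length(missing_tpl)) {
    stop("no template for type(s): ", paste(missing_tpl, collapse = ", "),
         call. = FALSE)
  }
  tpl <- stats::setNames(templates$template, templates$type_id)
  subj <- unname(names[records$subject_id])
  obj <- unname(names[records$object_id])
  if (anyNA(subj) || anyNA(obj)) {
    stop("compound name missing for some records", call. = FALSE)
  }
  out <- tpl[as.character(records$type_id)]
  out <- mapply(function(t, s, o) {
    gsub("{object}", o, gsub("{subject}", s, t, fixed = TRUE), fixed = TRUE)
  }, out, subj, obj, USE.NAMES = FALSE)
  out
}

#' Validate predicted drug-food interactions by structural similarity
#'
#' A predicted DFI is retained iff some approved drug is structurally similar
#' to the food compound (Dice >= `dice_min`, boundary inclusive) and the gold
#' standard contains an interaction of the same type involving that drug.
#'
#' @param records Predicted DFI records (each pairing one food compound with
#'   one drug).
#' @param dice_fd Dice matrix, food compounds (rows) x approved drugs
#'   (columns), e.g. from [dice_matrix()].
#' @param gold Gold-standard tibble.
#' @param food_ids Food compound IDs.
#' @param dice_min Similarity cutoff. Default 0.75.
#' @return Logical vector, one entry per record.
#' @export
validate_dfi <- function(records, dice_fd, gold, food_ids, dice_min = 0.75) {
  if (nrow(records) == 0) return(logical(0))
  # approved drugs with a gold record, per type
  drugs_by_type <- split(c(gold$subject_id, gold$object_id),
                         rep(gold$type_id, 2))
  drugs_by_type <- lapply(drugs_by_type,
                          function(d) intersect(unique(d), colnames(dice_fd)))
  food_side <- ifelse(records$subject_id %in% food_ids,
                      records$subject_id, records$object_id)
  vapply(seq_len(nrow(records)), function(i) {
    d <- drugs_by_type[[as.character(records$type_id[i])]]
    if (is.null(d) || length(d) == 0) return(FALSE)
    if (!food_side[i] %in% rownames(dice_fd)) return(FALSE)
    any(dice_fd[food_side[i], d] >= dice_min)
  }, logical(1))
}

#' Orientation of a drug-food interaction record
#'
#' Records with the food compound as the sentence subject indicate that the
#' compound may affect the drug's pharmacological effects
#' (`compound_affects_drug`); otherwise the drug modulates a bioactivity of
#' the compound (`drug_modulates_compound`).
#'
#' @param records DFI records tibble.
#' @param food_ids Food compound IDs.
#' @return Character vector of orientations.
#' @export
classify_dfi_orientation <- function(records, food_ids) {
  subj_food <- records$subject_id %in% food_ids
  obj_food <- records$object_id %in% food_ids
  if (any(subj_food == obj_food)) {
    stop("record(s) do not pair exactly one food compound with one drug",
         call. = FALSE)
  }
  ifelse(subj_food, "compound_affects_drug", "drug_modulates_compound")
}

#' Export predictions as TSV
#'
#' @param predictions A `ddi_predictions` object.
#' @param templates,names For sentence rendering.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_predictions <- function(predictions, templates, names, path) {
  rec <- predictions$records
  rec$sentence <- render_sentences(rec, templates, names)
  readr::write_tsv(rec, path)
  invisible(path)
}
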