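# Loading and validation of the drug registry, the gold-standard interaction
# set, sentence templates, food-composition tables and patient medication
# plans. File schemas are deliberately simple tabular text (TSV/CSV).

.REGISTRY_COLS <- c("id", "name", "smiles", "approved", "targets", "category")

#' Load a drug registry
#'
#' Reads a TSV with columns `id`, `name`, `smiles`, `approved`, `targets`
#' (semicolon-separated `target:action` pairs) and `category` (one of
#' `non_dmd`, `dmd`, `btki`, `other`). Structures are canonicalized; records
#' whose SMILES cannot be parsed are retained but flagged structure-less and
#' excluded from prediction.
#'
#' @param path TSV file path, or a data frame with the same columns.
#' @return Tibble with columns `drug_id`, `name`, `smiles`,
#'   `canonical_smiles`, `approved`, `targets`, `category`, `has_structure`.
#' @export
load_registry <- function(path) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  }
  missing <- setdiff(.REGISTRY_COLS, names(raw))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$id)) {
    stop("duplicate drug IDs in registry: ",
         paste(unique(raw$id[duplicated(raw$id)]), collapse = ", "),
         call. = FALSE)
  }
  can <- canonical_smiles(as.character(raw$smiles))
  tibble::tibble(
    drug_id = as.character(raw$id),
    name = as.character(raw$name),
    smiles = as.character(raw$smiles),
    canonical_smiles = can,
    approved = as.logical(raw$approved),
    targets = as.character(raw$targets),
    category = as.character(raw$category),
    has_structure = !is.na(can))
}

#' Parse a serialized target-action annotation
#'
#' @param targets Character vector like `"T01:inhibitor;T02:agonist"`.
#' @return List of sorted character vectors of `target:action` pairs (the
#'   normalized set representation used for alternative-drug matching).
#' @export
parse_target_sets <- function(targets) {
  lapply(targets, function(t) {
    if (is.na(t) || !nzchar(trimws(t))) return(character(0))
    sort(unique(trimws(strsplit(t, ";", fixed = TRUE)[[1]])))
  })
}

#' Load raw interaction records
#'
#' @param path TSV with columns `subject_id`, `object_id`, `type_id`, or a
#'   data frame with those columns.
#' @return Tibble with `subject_id`, `object_id`, `type_id` (integer),
#'   `provenance = "gold"`, `score = 1`.
#' @export
load_interactions <- function(path) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_tsv(path, col_types = readr::cols(
      subject_id = readr::col_character(),
      object_id = readr::col_character(),
      type_id = readr::col_integer()))
  }
  missing <- setdiff(c("subject_id", "object_id", "type_id"), names(raw))
  if (length(missing)) {
    stop("interactions table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(subject_id = as.character(raw$subject_id),
                 object_id = as.character(raw$object_id),
                 type_id = as.integer(raw$type_id),
                 provenance = "gold", score = 1)
}

#' Filter raw interactions into the gold standard
#'
#' Retains exactly the records where both drugs have a parseable structure and
#' the type identifier lies in `1..n_types`; everything else is dropped with a
#' recorded reason (`no_structure`, `unknown_type`, `unknown_drug`).
#'
#' @param interactions Tibble from [load_interactions()].
#' @param registry Tibble from [load_registry()].
#' @param n_types Number of modelled interaction types. Default 86.
#' @return List with `gold` (retained tibble), `dropped` (tibble with a
#'   `reason` column) and `drop_counts` (named integer vector).
#' @export
filter_gold_standard <- function(interactions, registry, n_types = 86L) {
  known <- interactions$subject_id %in% registry$drug_id &
    interactions$object_id %in% registry$drug_id
  has_struct <- stats::setNames(registry$has_structure, registry$drug_id)
  structured <- known &
    !is.na(has_struct[interactions$subject_id]) &
    !is.na(has_struct[interactions$object_id]) &
    has_struct[interactions$subject_id] &
    has_struct[interactions$object_id]
  valid_type <- !is.na(interactions$type_id) &
    interactions$type_id >= 1L & interactions$type_id <= n_types
  reason <- rep(NA_character_, nrow(interactions))
  reason[!valid_type] <- "unknown_type"
  reason[valid_type & known & !structured] <- "no_structure"
  reason[valid_type & !known] <- "unknown_drug"
  keep <- is.na(reason)
  dropped <- interactions[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  counts <- table(factor(dropped$reason,
                         levels = c("no_structure", "unknown_type", "unknown_drug")))
  list(gold = interactions[keep, , drop = FALSE],
       dropped = dropped,
       drop_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Percentage of records retained by a filter
#'
#' @param n_retained,n_total Record counts.
#' @param digits Decimal places. Default 1.
#' @return Retention percentage.
#' @export
retention_percent <- function(n_retained, n_total, digits = 1) {
  stopifnot(n_total > 0, n_retained >= 0, n_retained <= n_total)
  round(100 * n_retained / n_total, digits)
}

#' Split records into training, validation and test partitions
#'
#' Random disjoint partitions of the record rows. The validation and test
#' partitions receive `floor(N * fraction)` records each and the remainder
#' goes to the training partition, so a 60/20/20 split of 1,046,705 records
#' yields 628,023 / 209,341 / 209,341.
#'
#' @param records Data frame of records (typically the gold standard).
#' @param fractions Numeric length-3 vector summing to 1. Default
#'   `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with data frames `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.6, 0.2, 0.2), seed = 0L) {
  stopifnot(is.data.frame(records), length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- nrow(records)
  if (n == 0) stop("cannot split an empty record set", call. = FALSE)
  n_val <- floor(n * fractions[2])
  n_test <- floor(n * fractions[3])
  perm <- withr::with_seed(seed, sample.int(n))
  idx_val <- perm[seq_len(n_val)]
  idx_test <- perm[n_val + seq_len(n_test)]
  idx_train <- perm[setdiff(seq_len(n), seq_len(n_val + n_test))]
  list(train = records[idx_train, , drop = FALSE],
       validation = records[idx_val, , drop = FALSE],
       test = records[idx_test, , drop = FALSE])
}

#' Load sentence templates
#'
#' @param path CSV with columns `type_id`, `critical`, `template`, or `NULL`
#'   for [default_templates()].
#' @param n_types Expected number of types. Default 86.
#' @return Tibble with one row per type.
#' @export
load_templates <- function(path = NULL, n_types = 86L) {
  if (is.null(path)) return(default_templates(n_types))
  tpl <- readr::read_csv(path, col_types = readr::cols(
    type_id = readr::col_integer(),
    critical = readr::col_logical(),
    template = readr::col_character()))
  if (anyDuplicated(tpl$type_id)) stop("duplicate template type_id", call. = FALSE)
  if (!setequal(tpl$type_id, seq_len(n_types))) {
    stop("templates must cover exactly types 1..", n_types, call. = FALSE)
  }
  bad <- !grepl("{subject}", tpl$template, fixed = TRUE) |
    !grepl("{object}", tpl$template, fixed = TRUE)
  if (any(bad)) {
    stop("template(s) without both {subject} and {object} slots: ",
         paste(tpl$type_id[bad], collapse = ", "), call. = FALSE)
  }
  dplyr::arrange(tpl, .data$type_id)
}

#' Load food compounds and content tables
#'
#' @param compounds_path CSV with columns `compound_id`, `name`, `smiles` (or
#'   a data frame).
#' @param contents_path CSV with columns `source_id`, `source_name`,
#'   `compound_id`, `amount_mg_per_100g` (or a data frame).
#' @return List with `compounds` (canonicalized, `has_structure` flagged) and
#'   `contents` tibbles. Negative amounts are rejected.
#' @export
load_food_db <- function(compounds_path, contents_path) {
  comp <- if (is.data.frame(compounds_path)) {
    tibble::as_tibble(compounds_path)
  } else {
    readr::read_csv(compounds_path,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  stopifnot(all(c("compound_id", "name", "smiles") %in% names(comp)))
  if (anyDuplicated(comp$compound_id)) {
    stop("duplicate food compound IDs", call. = FALSE)
  }
  can <- canonical_smiles(as.character(comp$smiles))
  compounds <- tibble::tibble(compound_id = as.character(comp$compound_id),
                              name = as.character(comp$name),
                              smiles = as.character(comp$smiles),
                              canonical_smiles = can,
                              has_structure = !is.na(can))
  cont <- if (is.data.frame(contents_path)) {
    tibble::as_tibble(contents_path)
  } else {
    readr::read_csv(contents_path, col_types = readr::cols(
      source_id = readr::col_character(),
      source_name = readr::col_character(),
      compound_id = readr::col_character(),
      amount_mg_per_100g = readr::col_double()))
  }
  stopifnot(all(c("source_id", "source_name", "compound_id",
                  "amount_mg_per_100g") %in% names(cont)))
  if (any(cont$amount_mg_per_100g < 0, na.rm = TRUE)) {
    stop("negative food content amounts", call. = FALSE)
  }
  list(compounds = compounds, contents = tibble::as_tibble(cont))
}

#' Load patient medication plans
#'
#' @param path CSV with columns `patient_id`, `course`, `drugs` (semicolon
#'   separated drug IDs), or a data frame.
#' @param registry Optional registry for validating drug IDs.
#' @return Tibble with `patient_id`, `course` and a list-column `drug_ids`
#'   (duplicates within a plan are removed: plans are sets).
#' @export
load_plans <- function(path, registry = NULL) {
  raw <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  }
  stopifnot(all(c("patient_id", "course", "drugs") %in% names(raw)))
  drug_ids <- lapply(raw$drugs, function(d) {
    if (is.na(d) || !nzchar(trimws(d))) return(character(0))
    unique(trimws(strsplit(d, ";", fixed = TRUE)[[1]]))
  })
  plans <- tibble::tibble(patient_id = as.character(raw$patient_id),
                          course = as.character(raw$course),
                          drug_ids = drug_ids)
  if (!is.null(registry)) {
    unknown <- setdiff(unlist(drug_ids), registry$drug_id)
    if (length(unknown)) {
      stop("medication plans reference unknown drug ID(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  plans
}
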