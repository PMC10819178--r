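#' Critical DDI type identifiers
#'
#' The 14 interaction types regarded as having clear negative health effects:
#' types 18--23 and 25--32. These drive the substitution safety check in
#' [suggest_substitutions()].
#'
#' @return Integer vector of length 14.
#' @export
#' @examples
#' critical_types()
critical_types <- function() {
  as.integer(c(18:23, 25:32))
}

#' Concentration-altering DFI type sets
#'
#' Interaction types describing a change in a drug's absorption (1, 2),
#' bioavailability (4, 5), metabolism (6, 7) or serum concentration (9, 10).
#' Types 1, 4, 7 and 9 imply a decreased and types 2, 5, 6 and 10 an
#' increased in vivo drug concentration.
#'
#' @return Named list with integer vectors `decrease`, `increase` and `all`.
#' @export
concentration_types <- function() {
  dec <- as.integer(c(1, 4, 7, 9))
  inc <- as.integer(c(2, 5, 6, 10))
  list(decrease = dec, increase = inc, all = sort(c(dec, inc)))
}

#' Pipeline configuration
#'
#' Bundles every numeric constant of the prediction pipeline: fingerprint
#' parameters, the reduced profile dimension, the prediction and safety
#' thresholds, the structural-validation cutoff for drug-food interactions and
#' the food-source ranking depth.
#'
#' @param radius Morgan fingerprint radius (bond steps). Default 2.
#' @param n_bits Hashed fingerprint width. Default 2048.
#' @param k Reduced dimension of the structural similarity profile. Default 50,
#'   giving pair feature vectors of length `2 * k = 100`.
#' @param threshold_default Output-neuron activation threshold at which a type
#'   counts as predicted. Default 0.47.
#' @param threshold_screen Doubled high-confidence threshold used for the final
#'   screening predictions. Default 0.94.
#' @param safety_threshold Maximum tolerated critical-type activation for a
#'   substitution suggestion. Default 0.47.
#' @param dice_min Minimum Dice similarity between a food compound and an
#'   approved drug for a predicted DFI to be retained. Default 0.75.
#' @param top_k_sources Number of richest food sources reported per food
#'   compound. Default 10.
#' @return A list of class `ddi_pipeline_config`.
#' @export
pipeline_config <- function(radius = 2L, n_bits = 2048L, k = 50L,
                            threshold_default = 0.47, threshold_screen = 0.94,
                            safety_threshold = 0.47, dice_min = 0.75,
                            top_k_sources = 10L) {
  stopifnot(radius >= 0, n_bits > 0, k > 0,
            threshold_default > 0, threshold_default < 1,
            threshold_screen > 0, threshold_screen < 1,
            dice_min >= 0, dice_min <= 1, top_k_sources > 0)
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits),
                 k = as.integer(k), threshold_default = threshold_default,
                 threshold_screen = threshold_screen,
                 safety_threshold = safety_threshold, dice_min = dice_min,
                 top_k_sources = as.integer(top_k_sources)),
            class = "ddi_pipeline_config")
}

# Sentence texts for the interaction types whose wording is pinned by the
# DeepDDI sentence catalogue; all other types carry a generic placeholder.
.pinned_templates <- function() {
  c(`3`  = "The absorption of {object} can be decreased when combined with {subject}.",
    `6`  = "The metabolism of {object} can be decreased when combined with {subject}.",
    `7`  = "The metabolism of {object} can be increased when combined with {subject}.",
    `9`  = "The serum concentration of {object} can be decreased when combined with {subject}.",
    `10` = "The serum concentration of {object} can be increased when combined with {subject}.",
    `15` = "{subject} may decrease the excretion rate of {object} which could result in a higher serum level.",
    `20` = "{subject} may increase the hepatotoxic activities of {object}.",
    `26` = "The risk or severity of adverse effects can be increased when {subject} is combined with {object}.",
    `27` = "The risk or severity of bleeding can be increased when {subject} is combined with {object}.",
    `29` = "The risk or severity of hyperkalemia can be increased when {subject} is combined with {object}.",
    `32` = "The risk or severity of QTc prolongation can be increased when {subject} is combined with {object}.",
    `52` = "{subject} may increase the bradycardic activities of {object}.",
    `54` = "{subject} may increase the central nervous system depressant activities of {object}.",
    `67` = "{subject} may increase the hypotensive activities of {object}.")
}

#' Sentence templates for the 86 interaction types
#'
#' One template per type, each with `{subject}` and `{object}` slots. Types
#' whose sentence wording is part of the published catalogue carry that text;
#' the remaining types carry a generic placeholder sentence that can be
#' replaced by loading a full template table with [load_templates()].
#'
#' @param n_types Number of interaction types. Default 86.
#' @return Tibble with columns `type_id`, `critical`, `template`.
#' @export
#' @examples
#' tpl <- default_templates()
#' sum(tpl$critical)  # 14 critical types
default_templates <- function(n_types = 86L) {
  pinned <- .pinned_templates()
  type_id <- seq_len(n_types)
  template <- sprintf(
    "An interaction of type %d may occur when {subject} is combined with {object}.",
    type_id)
  idx <- as.integer(names(pinned))
  idx <- idx[idx <= n_types]
  template[idx] <- unname(pinned[as.character(idx)])
  tibble::tibble(type_id = as.integer(type_id),
                 critical = type_id %in% critical_types(),
                 template = template)
}
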