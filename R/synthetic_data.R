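# Desk-scale synthetic study data. Drugs are enumerated from a
# scaffold-by-substituent grammar; the scaffold pair determines the gold
# interaction type through a fixed rule table (so structurally similar drugs
# have similar interaction patterns, the working assumption of the
# classifier), while the substituent acts as the pharmacophore that fixes a
# drug's target-action set (so substitution candidates exist across
# scaffolds). Cohorts draw medication counts from a truncated negative
# binomial matched to mean 5.3, SD 3.3 on [0, 19].

.SCAFFOLDS <- c(
  benzene     = "c1ccc(%s)cc1",
  piperidine  = "C1CCN(%s)CC1",
  indole      = "c1ccc2[nH]c(%s)cc2c1",
  cyclohexane = "C1CCC(%s)CC1",
  pyridine    = "c1cc(%s)ccn1",
  benzoate    = "O=C(O)c1ccc(%s)cc1",
  naphthalene = "c1ccc2cc(%s)ccc2c1",
  morpholine  = "O1CCN(%s)CC1",
  furan       = "c1cc(%s)oc1",
  thiophene   = "c1cc(%s)sc1",
  piperazine  = "C1CN(%s)CCN1C",
  oxane       = "O1CCC(%s)CC1")

.SUBSTITUENTS <- c("C", "CC", "CCC", "CCCC", "C(C)C", "CO", "CCO", "CCCO",
                   "CN", "CCN", "C(=O)O", "CC(=O)O", "C(=O)N", "Cl", "F",
                   "CCl", "CF", "C(F)F", "CS", "COC", "CCOC", "CC#N", "C=C",
                   "CC=C", "C(C)O")

.ACTIONS <- c("inhibitor", "agonist", "antagonist", "modulator")

.NAME_SYLLABLES <- list(
  pre = c("al", "bex", "cor", "dal", "ery", "fex", "gly", "hyl", "iso", "jan",
          "kel", "lor", "mex", "nor", "oxa", "pra", "quin", "rev", "sol",
          "tev", "ulo", "van", "wex", "xan", "yel", "zor"),
  suf = c("amide", "azine", "idine", "ine", "ol", "one", "oril", "umab",
          "utinib", "afil", "oprol", "astat"))

#' Scenario configuration for the synthetic study
#'
#' Defaults reproduce the study conditions the analyses assume: 300 drugs, a
#' gold-pair sampling density giving roughly 10,000 interactions, a cohort of
#' 627 patients taking 0--19 concurrent medications with mean 5.3 and SD 3.3,
#' 6 disease-modifying drugs (DMDs), 5 investigational BTK inhibitors (with
#' no gold interactions of their own), 150 food compounds and 80 food
#' sources.
#'
#' @param n_drugs Number of drugs (at most `12 * 25`, the grammar capacity).
#' @param n_types Number of interaction types modelled. Default 86.
#' @param gold_density Fraction of eligible unordered drug pairs recorded in
#'   the gold standard. The default 0.23 places the cohort's gold-based
#'   interaction prevalence inside the 70--85% design bracket.
#' @param n_patients Cohort size. Default 627.
#' @param med_mean,med_sd,med_max Medication-count moments and hard range cap.
#' @param dmd_share Fraction of patients on a DMD. Default 0.62.
#' @param n_dmd,n_btki Number of DMD / BTKi drugs in the registry.
#' @param approved_rate Approval probability for ordinary drugs. Default 0.85.
#' @param n_food_compounds,n_food_sources Food database size.
#' @param analog_fraction Fraction of food compounds that are structural
#'   analogs of approved drugs (these make the DFI validation step fire).
#' @param seed Master seed; all generators derive from it deterministically.
#' @return A list of class `ddi_scenario_config`.
#' @export
scenario_config <- function(n_drugs = 300L, n_types = 86L,
                            gold_density = 0.23, n_patients = 627L,
                            med_mean = 5.3, med_sd = 3.3, med_max = 19L,
                            dmd_share = 0.62, n_dmd = 6L, n_btki = 5L,
                            approved_rate = 0.85, n_food_compounds = 150L,
                            n_food_sources = 80L, analog_fraction = 0.2,
                            seed = 42L) {
  stopifnot(n_drugs >= 2, n_drugs <= length(.SCAFFOLDS) * length(.SUBSTITUENTS),
            n_types >= 1, n_types <= 86, gold_density > 0, gold_density <= 1,
            n_patients >= 1, med_max >= 1, n_dmd >= 0, n_btki >= 0,
            n_food_compounds >= 1, n_food_sources >= 1,
            analog_fraction >= 0, analog_fraction <= 1)
  structure(list(n_drugs = as.integer(n_drugs), n_types = as.integer(n_types),
                 gold_density = gold_density,
                 n_patients = as.integer(n_patients), med_mean = med_mean,
                 med_sd = med_sd, med_max = as.integer(med_max),
                 dmd_share = dmd_share, n_dmd = as.integer(n_dmd),
                 n_btki = as.integer(n_btki), approved_rate = approved_rate,
                 n_food_compounds = as.integer(n_food_compounds),
                 n_food_sources = as.integer(n_food_sources),
                 analog_fraction = analog_fraction, seed = as.integer(seed)),
            class = "ddi_scenario_config")
}

#' Ordered rule table mapping scaffold pairs to interaction types
#'
#' A fixed `12 x 12` matrix `R` where `R[i, j]` is the interaction type of a
#' drug pair whose subject has scaffold class `i` and object scaffold class
#' `j`. Most cells are symmetric. A few designated cells are directional:
#' the forward order carries type 26 (increased risk or severity of adverse
#' effects) and the reverse order a mechanistic type — these produce the
#' genuine multi-type pair predictions the mechanism-inference analysis looks
#' for. Other designated cells carry critical types (hepatotoxicity,
#' bleeding, hyperkalemia, QTc prolongation, ...) and the eight
#' concentration-altering types used by the food-interaction network.
#'
#' @return Integer matrix with attribute `directional` (logical matrix).
#' @export
ddi_rule_table <- function() {
  ns <- length(.SCAFFOLDS)
  filler <- c(15L, 6L, 26L, 15L, 54L, 6L, 67L, 15L, 39L, 43L, 6L, 47L, 61L,
              15L, 73L, 80L, 33L, 6L, 36L, 41L, 15L, 26L, 54L, 67L)
  R <- matrix(0L, ns, ns)
  f <- 1L
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      R[i, j] <- R[j, i] <- filler[(f - 1L) %% length(filler) + 1L]
      f <- f + 1L
    }
  }
  directional <- matrix(FALSE, ns, ns)
  set_sym <- function(i, j, type) R[i, j] <<- R[j, i] <<- type
  # critical cells
  set_sym(1, 2, 20L); set_sym(3, 5, 27L); set_sym(2, 4, 29L)
  set_sym(5, 7, 32L); set_sym(6, 9, 21L); set_sym(8, 10, 23L)
  # concentration-altering cells (types 1,2,4,5,6,7,9,10)
  set_sym(1, 4, 9L); set_sym(2, 3, 6L); set_sym(3, 7, 10L)
  set_sym(4, 8, 1L); set_sym(5, 9, 2L); set_sym(6, 10, 4L)
  set_sym(7, 11, 5L); set_sym(8, 11, 7L)
  # directional cells: forward type 26, reverse a mechanism type
  dir_cells <- list(c(1, 3, 6L), c(2, 5, 9L), c(4, 7, 15L), c(6, 8, 3L))
  for (d in dir_cells) {
    R[d[1], d[2]] <- 26L
    R[d[2], d[1]] <- d[3]
    directional[d[1], d[2]] <- directional[d[2], d[1]] <- TRUE
  }
  attr(R, "directional") <- directional
  R
}

.gen_names <- function(n, seed) {
  withr::with_seed(seed, {
    nm <- character(n)
    for (i in seq_len(n)) {
      nm[i] <- paste0(sample(.NAME_SYLLABLES$pre, 1),
                      sample(.NAME_SYLLABLES$pre, 1),
                      sample(.NAME_SYLLABLES$suf, 1))
    }
    nm <- make.unique(nm, sep = "")
    paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
  })
}

# target-action set for a substituent (pharmacophore) class, serialized
.class_targets <- function(sub_class, btki_class = NA) {
  vapply(sub_class, function(cls) {
    if (!is.na(btki_class) && cls == btki_class) return("BTK:inhibitor")
    t1 <- sprintf("T%02d:%s", cls, .ACTIONS[(cls %% length(.ACTIONS)) + 1])
    if (cls %% 3 == 0) {
      paste(t1, sprintf("T%02d:%s", 25 + cls %/% 3,
                        .ACTIONS[(cls %% 2) + 1]), sep = ";")
    } else {
      t1
    }
  }, "")
}

#' Generate a synthetic drug registry
#'
#' Drugs are unique scaffold-substituent combinations with valid SMILES. The
#' registry carries the generator's motif annotations (`scaffold_class`,
#' `sub_class`) alongside the standard registry columns; drugs sharing a
#' substituent class share their target-action set. `n_dmd` drugs of one
#' substituent class are flagged as approved disease-modifying drugs and
#' `n_btki` drugs of another as unapproved investigational BTK inhibitors.
#'
#' @param cfg A [scenario_config()].
#' @return Registry tibble (see [load_registry()]) with extra columns
#'   `scaffold_class` and `sub_class`.
#' @export
gen_drug_library <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "ddi_scenario_config"))
  stopifnot(cfg$n_drugs >= cfg$n_dmd + cfg$n_btki + 2)
  withr::with_seed(cfg$seed + 1L, {
    grid <- expand.grid(scaf = seq_along(.SCAFFOLDS),
                        sub = seq_along(.SUBSTITUENTS))
    # the DMD and BTKi pharmacophore classes are seated first so they always
    # reach their configured sizes; the rest of the library is a uniform
    # sample of the remaining scaffold-substituent combinations
    cls_order <- sample(seq_along(.SUBSTITUENTS))
    dmd_class <- cls_order[1]
    btki_class <- cls_order[2]
    pick_class <- function(cls, k) {
      rows <- which(grid$sub == cls)
      grid[sample(rows, min(k, length(rows))), ]
    }
    seated <- rbind(pick_class(dmd_class, cfg$n_dmd),
                    pick_class(btki_class, cfg$n_btki))
    rest_pool <- setdiff(seq_len(nrow(grid)), as.integer(rownames(seated)))
    rest <- grid[sample(rest_pool, cfg$n_drugs - nrow(seated)), ]
    take <- rbind(seated, rest)
    take <- take[sample.int(nrow(take)), ]
    # construction guarantee: at least two drugs share a pharmacophore class
    if (cfg$n_drugs >= 2 && !anyDuplicated(take$sub)) {
      alt <- which(grid$sub == take$sub[1] & grid$scaf != take$scaf[1])[1]
      take[2, ] <- grid[alt, ]
    }
    smiles <- sprintf(.SCAFFOLDS[take$scaf], .SUBSTITUENTS[take$sub])
    n <- cfg$n_drugs
    dmd_idx <- utils::head(which(take$sub == dmd_class), cfg$n_dmd)
    btki_idx <- utils::head(which(take$sub == btki_class), cfg$n_btki)
    category <- rep("non_dmd", n)
    category[dmd_idx] <- "dmd"
    category[btki_idx] <- "btki"
    approved <- stats::runif(n) < cfg$approved_rate
    approved[dmd_idx] <- TRUE
    approved[btki_idx] <- FALSE
    raw <- tibble::tibble(
      id = sprintf("D%03d", seq_len(n)),
      name = .gen_names(n, cfg$seed + 2L),
      smiles = smiles,
      approved = approved,
      targets = .class_targets(take$sub, btki_class),
      category = category)
    reg <- load_registry(raw)
    reg$scaffold_class <- as.integer(take$scaf)
    reg$sub_class <- as.integer(take$sub)
    reg
  })
}

#' Gold label for one drug pair under the rule table
#'
#' Applies the deterministic labelling rule: the subject drug is chosen from
#' the pair's motif classes (for directional scaffold cells, by the parity of
#' the lower-scaffold drug's substituent class; otherwise the lower-scaffold
#' or lower-ID drug), and the type is the rule-table entry for the resulting
#' ordered scaffold pair.
#'
#' @param registry Registry with `scaffold_class`/`sub_class` columns.
#' @param drug_a,drug_b Drug IDs.
#' @param rule Rule table from [ddi_rule_table()].
#' @return List with `subject_id`, `object_id`, `type_id`.
#' @export
gold_label_for_pair <- function(registry, drug_a, drug_b,
                                rule = ddi_rule_table()) {
  ra <- registry[registry$drug_id == drug_a, ]
  rb <- registry[registry$drug_id == drug_b, ]
  stopifnot(nrow(ra) == 1, nrow(rb) == 1)
  directional <- attr(rule, "directional")
  if (ra$scaffold_class == rb$scaffold_class) {
    first <- if (drug_a < drug_b) ra else rb
    second <- if (drug_a < drug_b) rb else ra
  } else {
    lo <- if (ra$scaffold_class < rb$scaffold_class) ra else rb
    hi <- if (ra$scaffold_class < rb$scaffold_class) rb else ra
    if (directional[lo$scaffold_class, hi$scaffold_class] &&
        lo$sub_class %% 2 == 1) {
      first <- hi; second <- lo
    } else {
      first <- lo; second <- hi
    }
  }
  list(subject_id = first$drug_id, object_id = second$drug_id,
       type_id = rule[first$scaffold_class, second$scaffold_class])
}

#' Generate the synthetic gold-standard interaction set
#'
#' Samples unordered pairs of structure-bearing, non-BTKi drugs at the
#' configured density and labels each with exactly one type via
#' [gold_label_for_pair()]. BTK inhibitors have no gold records; all their
#' interactions are model-predicted, mirroring their investigational status.
#'
#' @param registry Registry from [gen_drug_library()].
#' @param cfg A [scenario_config()].
#' @return Gold-standard tibble (`subject_id`, `object_id`, `type_id`,
#'   `provenance`, `score`).
#' @export
gen_gold_standard <- function(registry, cfg = scenario_config()) {
  eligible <- registry$drug_id[registry$has_structure &
                                 registry$category != "btki"]
  stopifnot(length(eligible) >= 2)
  rule <- ddi_rule_table()
  pairs <- t(utils::combn(sort(eligible), 2))
  withr::with_seed(cfg$seed + 3L, {
    keep <- stats::runif(nrow(pairs)) < cfg$gold_density
  })
  pairs <- pairs[keep, , drop = FALSE]
  scaf <- stats::setNames(registry$scaffold_class, registry$drug_id)
  subc <- stats::setNames(registry$sub_class, registry$drug_id)
  directional <- attr(rule, "directional")
  a <- pairs[, 1]; b <- pairs[, 2]
  sa <- scaf[a]; sb <- scaf[b]
  lo_is_a <- sa < sb | (sa == sb & a < b)
  lo <- ifelse(lo_is_a, a, b); hi <- ifelse(lo_is_a, b, a)
  slo <- pmin(sa, sb); shi <- pmax(sa, sb)
  flip <- directional[cbind(slo, shi)] & subc[lo] %% 2 == 1
  subject <- ifelse(flip, hi, lo)
  object <- ifelse(flip, lo, hi)
  tibble::tibble(subject_id = unname(subject), object_id = unname(object),
                 type_id = unname(rule[cbind(scaf[subject], scaf[object])]),
                 provenance = "gold", score = 1)
}

# truncated-negative-binomial pmf on 0..max_n
.trunc_nb_pmf <- function(mu, size, max_n) {
  p <- stats::dnbinom(0:max_n, size = size, mu = mu)
  p / sum(p)
}

#' Moment-match a truncated negative binomial
#'
#' Finds `(mu, size)` such that the negative binomial truncated to
#' `[0, max_n]` has the target mean and standard deviation. Used for the
#' medication-count distribution (overdispersed counts with a hard range).
#'
#' @param mean,sd Target moments.
#' @param max_n Upper truncation bound.
#' @return List with `mu`, `size`, `pmf` (on `0:max_n`) and the achieved
#'   `mean` and `sd`.
#' @export
fit_truncated_nbinom <- function(mean = 5.3, sd = 3.3, max_n = 19L) {
  obj <- function(par) {
    mu <- exp(par[1]); size <- exp(par[2])
    p <- .trunc_nb_pmf(mu, size, max_n)
    m <- sum((0:max_n) * p)
    s <- sqrt(sum((0:max_n)^2 * p) - m^2)
    (m - mean)^2 + (s - sd)^2
  }
  fit <- stats::optim(c(log(mean), log(mean^2 / max(sd^2 - mean, 0.1))), obj)
  mu <- exp(fit$par[1]); size <- exp(fit$par[2])
  p <- .trunc_nb_pmf(mu, size, max_n)
  m <- sum((0:max_n) * p)
  list(mu = mu, size = size, pmf = p, mean = m,
       sd = sqrt(sum((0:max_n)^2 * p) - m^2))
}

.COURSES <- c(CIS = 27, RRMS = 388, SPMS = 154, PPMS = 58)

#' Generate a synthetic patient cohort
#'
#' Per-patient medication counts are drawn from the moment-matched truncated
#' negative binomial on `[0, med_max]`; a configurable share of patients
#' receive one DMD, the rest of each plan is filled with ordinary drugs.
#' Disease-course labels follow the configured mixture. BTK inhibitors never
#' appear in plans (they are investigational).
#'
#' @param registry Registry from [gen_drug_library()].
#' @param cfg A [scenario_config()].
#' @return Plans tibble (`patient_id`, `course`, `drug_ids` list-column).
#' @export
gen_cohort <- function(registry, cfg = scenario_config()) {
  nb <- fit_truncated_nbinom(cfg$med_mean, cfg$med_sd, cfg$med_max)
  ordinary <- registry$drug_id[registry$category == "non_dmd" &
                                 registry$has_structure]
  dmds <- registry$drug_id[registry$category == "dmd"]
  withr::with_seed(cfg$seed + 4L, {
    m <- sample(0:cfg$med_max, cfg$n_patients, replace = TRUE, prob = nb$pmf)
    course <- sample(names(.COURSES), cfg$n_patients, replace = TRUE,
                     prob = .COURSES / sum(.COURSES))
    on_dmd <- stats::runif(cfg$n_patients) < cfg$dmd_share
    drug_ids <- lapply(seq_len(cfg$n_patients), function(i) {
      mi <- m[i]
      if (mi == 0) return(character(0))
      if (on_dmd[i] && length(dmds) > 0) {
        c(sample(dmds, 1),
          sample(ordinary, min(mi - 1, length(ordinary))))
      } else {
        sample(ordinary, min(mi, length(ordinary)))
      }
    })
    tibble::tibble(patient_id = sprintf("P%03d", seq_len(cfg$n_patients)),
                   course = course, drug_ids = drug_ids)
  })
}

.FOOD_SOURCES <- c(
  "corn", "cow's milk", "red bell pepper", "wheat", "oat", "barley", "rye",
  "rice", "potato", "tomato", "carrot", "onion", "garlic", "spinach",
  "broccoli", "cauliflower", "cabbage", "lettuce", "cucumber", "pumpkin",
  "apple", "pear", "peach", "apricot", "plum", "cherry", "strawberry",
  "raspberry", "blueberry", "cranberry", "grape", "orange", "lemon", "lime",
  "clementine", "grapefruit", "banana", "pineapple", "mango", "papaya",
  "walnut", "almond", "hazelnut", "peanut", "cashew", "pistachio",
  "sunflower seed", "flaxseed", "sesame", "soybean", "lentil", "chickpea",
  "pea", "bean", "salmon", "trout", "tuna", "herring", "mackerel", "cod",
  "shrimp", "mussel", "beef", "pork", "chicken", "turkey", "egg", "butter",
  "yogurt", "cheese", "honey", "cocoa", "coffee", "black tea", "green tea",
  "mushroom", "shiitake", "olive oil", "rapeseed oil", "ginger")

.food_grammar <- function() {
  polyols <- vapply(2:8, function(k) {
    paste0("OC", paste(rep("C(O)", k), collapse = ""), "CO")
  }, "")
  fatty <- vapply(3:14, function(k) {
    paste0(paste(rep("C", k), collapse = ""), "C(=O)O")
  }, "")
  phenolic <- c("Oc1ccc(C=CC(=O)O)cc1", "Oc1cc(O)cc(O)c1", "Oc1ccc(CO)cc1O",
                "Oc1ccc(C(=O)O)cc1O", "COc1cc(C=CC(=O)O)ccc1O",
                "Oc1ccc(CCO)cc1", "Oc1cc(C=CC(=O)O)cc(O)c1")
  amino <- c("NC(C)C(=O)O", "NCC(=O)O", "NC(CC(=O)O)C(=O)O",
             "NC(CCC(=O)O)C(=O)O", "NC(CO)C(=O)O", "NC(CS)C(=O)O",
             "NC(CC(C)C)C(=O)O", "NC(Cc1ccccc1)C(=O)O")
  terpene <- c("CC(C)=CCCC(C)=CC=O", "CC(C)=CCCC(C)=CCO", "CC1=CCC(CC1)C(C)C",
               "CC(C)C1CCC(C)CC1O", "CC(C)=CCC=C(C)C")
  esters <- as.vector(outer(c("C", "CC", "CCC"), c("C(=O)OC", "C(=O)OCC"),
                            paste0))
  unique(c(polyols, fatty, phenolic, amino, terpene, esters,
           "OCC1OC(O)C(O)C(O)C1O", "CN1C=NC2=C1C(=O)N(C)C(=O)N2C", "CCO",
           "OCC(O)CO", "C(C(=O)O)C(CC(=O)O)(O)C(=O)O"))
}

#' Generate a synthetic food database
#'
#' A configurable fraction of the compounds are structural analogs of
#' approved registry drugs (identical canonical structures under food-
#' compound identities), so the Dice >= 0.75 validation path of predicted
#' drug-food interactions fires; the remainder are food-like small molecules
#' (sugars, fatty acids, phenolics, amino acids, terpenes). Content rows give
#' positive amounts in mg per 100 g; the first compound is guaranteed at
#' least 11 sources so the top-10 truncation is exercised.
#'
#' @param registry Registry from [gen_drug_library()].
#' @param cfg A [scenario_config()].
#' @return List with `compounds` and `contents` tibbles (see
#'   [load_food_db()]).
#' @export
gen_food_db <- function(registry, cfg = scenario_config()) {
  withr::with_seed(cfg$seed + 5L, {
    n <- cfg$n_food_compounds
    n_analog <- round(n * cfg$analog_fraction)
    donors <- registry[registry$approved & registry$has_structure &
                         registry$category == "non_dmd", ]
    n_analog <- min(n_analog, nrow(donors))
    analog_smiles <- sample(donors$canonical_smiles, n_analog)
    pool <- .food_grammar()
    n_plain <- n - n_analog
    plain_smiles <- sample(pool, n_plain, replace = n_plain > length(pool))
    smiles <- c(analog_smiles, plain_smiles)
    ord <- sample.int(n)
    compounds <- tibble::tibble(
      compound_id = sprintf("F%03d", seq_len(n)),
      name = paste0(.gen_names(n, cfg$seed + 6L), " (food)"),
      smiles = smiles[ord],
      is_analog = c(rep(TRUE, n_analog), rep(FALSE, n_plain))[ord])
    can <- canonical_smiles(compounds$smiles)
    compounds$canonical_smiles <- can
    compounds$has_structure <- !is.na(can)
    n_src <- pmin(sample(3:10, n, replace = TRUE), cfg$n_food_sources)
    n_src[1] <- min(12L, cfg$n_food_sources)  # exercises top-10 truncation
    sources <- tibble::tibble(
      source_id = sprintf("S%02d", seq_len(cfg$n_food_sources)),
      source_name = rep_len(.FOOD_SOURCES, cfg$n_food_sources))
    contents <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      src <- sources[sample.int(nrow(sources), n_src[i]), ]
      tibble::tibble(source_id = src$source_id,
                     source_name = src$source_name,
                     compound_id = compounds$compound_id[i],
                     amount_mg_per_100g = stats::rlnorm(n_src[i], 2, 1.2))
    }))
    list(compounds = compounds, contents = contents)
  })
}

#' Generate a complete synthetic scenario
#'
#' @param cfg A [scenario_config()].
#' @return List with `registry`, `gold`, `plans`, `food` (compounds +
#'   contents), `templates`, `rule` and `cfg`.
#' @export
gen_scenario <- function(cfg = scenario_config()) {
  registry <- gen_drug_library(cfg)
  list(registry = registry,
       gold = gen_gold_standard(registry, cfg),
       plans = gen_cohort(registry, cfg),
       food = gen_food_db(registry, cfg),
       templates = default_templates(cfg$n_types),
       rule = ddi_rule_table(),
       cfg = cfg)
}

#' Write a scenario to the corpus file schemas
#'
#' Emits `registry.tsv`, `interactions.tsv`, `plans.csv`,
#' `food_compounds.csv`, `food_contents.csv`, `templates.csv` and a
#' `manifest.json` holding all scenario parameters.
#'
#' @param scenario From [gen_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- scenario$registry
  readr::write_tsv(tibble::tibble(id = reg$drug_id, name = reg$name,
                                  smiles = reg$smiles, approved = reg$approved,
                                  targets = reg$targets,
                                  category = reg$category),
                   file.path(dir, "registry.tsv"))
  readr::write_tsv(scenario$gold[, c("subject_id", "object_id", "type_id")],
                   file.path(dir, "interactions.tsv"))
  plans <- scenario$plans
  readr::write_csv(tibble::tibble(
    patient_id = plans$patient_id, course = plans$course,
    drugs = vapply(plans$drug_ids, paste, "", collapse = ";")),
    file.path(dir, "plans.csv"))
  readr::write_csv(scenario$food$compounds[, c("compound_id", "name", "smiles")],
                   file.path(dir, "food_compounds.csv"))
  readr::write_csv(scenario$food$contents, file.path(dir, "food_contents.csv"))
  readr::write_csv(scenario$templates, file.path(dir, "templates.csv"))
  jsonlite::write_json(unclass(scenario$cfg),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
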