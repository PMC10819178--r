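# Medication-plan screening, switch risk and the burden-vs-count trend.

toy_reg <- function() {
  load_registry(data.frame(
    id = c("A", "B", "C", "D", "M"),
    name = paste0("drug", 1:5),
    smiles = c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "CCS"),
    approved = TRUE,
    targets = "T1:inhibitor",
    category = c("non_dmd", "non_dmd", "non_dmd", "non_dmd", "dmd")))
}

test_that("plan pair enumeration matches the brute-force double loop", {
  expect_equal(nrow(enumerate_plan_pairs(c("A", "B"))), 1)
  expect_equal(nrow(enumerate_plan_pairs("A")), 0)
  expect_equal(nrow(enumerate_plan_pairs(character(0))), 0)
  p <- enumerate_plan_pairs(c("E", "A", "C", "B", "D"))
  expect_equal(nrow(p), 10)
  brute <- t(utils::combn(sort(c("A", "B", "C", "D", "E")), 2))
  expect_equal(as.matrix(p), brute, ignore_attr = TRUE)
  # drugs outside the predictable set are ignored
  expect_equal(nrow(enumerate_plan_pairs(c("A", "B", "X"),
                                         predictable = c("A", "B"))), 1)
})

test_that("cohort screening reproduces a hand tally with the pair/DDI distinction", {
  reg <- toy_reg()
  plans <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    course = "RRMS",
    drug_ids = list(c("A", "B", "C"), c("A", "B"), "C"))
  gold <- toy_records(c("A", "B"), c("B", "C"), c(6, 15), provenance = "gold")
  # P1 pair A-B fires two predicted types: 2 DDIs, 1 combination
  pred <- toy_records(c("A", "A", "A"), c("B", "B", "C"), c(6, 26, 15))
  rep <- screen_cohort(plans, gold, pred, reg)
  expect_equal(rep$per_patient$n_pairs, c(3, 1, 0))
  expect_equal(rep$total_pairs, 4)
  expect_equal(rep$per_patient$gold_ddis, c(2, 1, 0))
  expect_equal(rep$per_patient$pred_ddis, c(3, 2, 0))
  expect_equal(rep$per_patient$pred_combinations, c(2, 1, 0))
  expect_equal(rep$prevalence_gold, 2 / 3)
  expect_equal(rep$prevalence_pred, 2 / 3)
  expect_equal(rep$gold_total, 3)
  expect_equal(rep$pred_total, 5)
  # per-type frequencies sum to the DDI totals
  expect_equal(sum(rep$type_freq_gold$n), rep$gold_total)
  expect_equal(sum(rep$type_freq_pred$n), rep$pred_total)
  expect_equal(rep$type_freq_pred$n[rep$type_freq_pred$type_id == 6], 2L)
  expect_error(screen_cohort(tibble::tibble(patient_id = "P", course = "CIS",
                                            drug_ids = list("ZZ")),
                             gold, pred, reg), "ZZ")
})

test_that("a cohort without co-medication has zero prevalence", {
  reg <- toy_reg()
  plans <- tibble::tibble(patient_id = c("P1", "P2"), course = "CIS",
                          drug_ids = list("A", character(0)))
  rep <- screen_cohort(plans, toy_records(character(0), character(0),
                                          integer(0), provenance = "gold"),
                       toy_records(character(0), character(0), integer(0)),
                       reg)
  expect_equal(rep$prevalence_gold, 0)
  expect_equal(rep$prevalence_pred, 0)
})

test_that("cohort totals equal the sum of per-patient pair counts", {
  cfg <- scenario_config(n_drugs = 40, n_patients = 80, seed = 12)
  reg <- gen_drug_library(cfg)
  plans <- gen_cohort(reg, cfg)
  gold <- gen_gold_standard(reg, cfg)
  rep <- screen_cohort(plans, gold, toy_records(character(0), character(0),
                                                integer(0)), reg)
  predictable <- reg$drug_id[reg$has_structure]
  brute <- vapply(plans$drug_ids, function(ids) {
    m <- sum(ids %in% predictable)
    choose(m, 2)
  }, numeric(1))
  expect_equal(rep$per_patient$n_pairs, as.integer(brute))
  expect_equal(rep$total_pairs, sum(brute))
  expect_gte(rep$prevalence_gold, 0)
  expect_lte(rep$prevalence_gold, 1)
})

test_that("prediction-based prevalence dominates when predictions cover gold", {
  cfg <- scenario_config(n_drugs = 40, n_patients = 80, seed = 12)
  reg <- gen_drug_library(cfg)
  plans <- gen_cohort(reg, cfg)
  gold <- gen_gold_standard(reg, cfg)
  pred <- gold
  pred$provenance <- "predicted"
  extra <- toy_records(reg$drug_id[1], reg$drug_id[2], 54)
  rep <- screen_cohort(plans, gold, dplyr::bind_rows(pred, extra), reg)
  expect_gte(rep$prevalence_pred, rep$prevalence_gold)
})

test_that("switch risk removes current DMDs before adding the candidate", {
  reg <- toy_reg()  # M is the dmd
  plans <- tibble::tibble(
    patient_id = paste0("P", 1:4), course = "RRMS",
    drug_ids = list(c("A", "M"), c("A", "B"), c("A", "C"), c("B", "C")))
  # candidate X interacts (type 52) with A only; A is held by patients 1-3
  regX <- load_registry(data.frame(
    id = c("A", "B", "C", "M", "X"), name = paste0("d", 1:5),
    smiles = c("CCO", "CCN", "c1ccccc1", "CCS", "CCCO"), approved = TRUE,
    targets = "T1:inhibitor",
    category = c("non_dmd", "non_dmd", "non_dmd", "dmd", "dmd")))
  pred <- toy_records("X", "A", 52)
  expect_equal(switch_risk(plans, "X", 52, pred, regX), 3 / 4)
  # no interactions of the requested type -> 0
  expect_equal(switch_risk(plans, "X", 27, pred, regX), 0)
  # a patient whose only partner drug is their current DMD is not counted
  pred2 <- toy_records("X", "M", 52)
  expect_equal(switch_risk(plans, "X", 52, pred2, regX), 0)
  m <- switch_risk_matrix(plans, c("X", "M"), c(52, 27), pred, regX)
  expect_equal(dim(m), c(2, 2))
  expect_equal(m["X", "type_52"], 0.75)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("the burden trend fits an exponential with bootstrap band", {
  reg <- toy_reg()
  # increasing interaction density with medication count
  plans <- tibble::tibble(
    patient_id = paste0("P", 1:30), course = "RRMS",
    drug_ids = rep(list(c("A", "B"), c("A", "B", "C"), c("A", "B", "C", "D")),
                   10))
  gold <- toy_records(character(0), character(0), integer(0),
                      provenance = "gold")
  pred <- toy_records(c("A", "A", "B", "C"), c("B", "C", "C", "D"),
                      c(6, 15, 26, 54))
  rep <- screen_cohort(plans, gold, pred, reg)
  tr <- ddi_count_vs_medications(rep, n_boot = 50)
  expect_gt(tr$fit["slope"], 0)
  expect_true(all(tr$curve$lo <= tr$curve$hi))
  # counts are bounded by types-per-pair times the pair count
  max_types <- max(table(paste(pred$subject_id, pred$object_id)))
  expect_true(all(rep$per_patient$pred_ddis <=
                    max_types * choose(rep$per_patient$n_pairs * 2, 2)))
  expect_true(all(rep$per_patient$pred_ddis <=
                    max_types * rep$per_patient$n_pairs))
  # degenerate cohort: fewer than 3 distinct medication counts
  plans2 <- plans[rep(1, 5), ]
  rep2 <- screen_cohort(plans2, gold, pred, reg)
  expect_warning(tr2 <- ddi_count_vs_medications(rep2), "skipped")
  expect_null(tr2$fit)
})

test_that("cohort reports export as JSON and CSV", {
  reg <- toy_reg()
  plans <- tibble::tibble(patient_id = "P1", course = "RRMS",
                          drug_ids = list(c("A", "B")))
  rep <- screen_cohort(plans, toy_records("A", "B", 6, provenance = "gold"),
                       toy_records("A", "B", 6), reg)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  export_cohort_report(rep, jp, cp)
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$prevalence_gold, 1)
  expect_equal(nrow(readr::read_csv(cp, show_col_types = FALSE)), 86)
})
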