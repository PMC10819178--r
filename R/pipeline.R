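# End-to-end orchestration of the synthetic study: featurization, training,
# prediction, cohort screening and the three downstream clinical analyses.

#' Desk-scale classifier configuration
#'
#' The reference architecture (nine hidden batch-normalized ReLU layers,
#' sigmoid head, Adam at 0.001, 20 epochs) at reduced width, sized for the
#' synthetic scenario: 128 units per hidden layer and minibatches of 256.
#'
#' @param input_dim Pair-feature length. Default 100.
#' @param output_dim Number of types. Default 86.
#' @param seed Training seed.
#' @return A `ddi_model_config`.
#' @export
desk_model_config <- function(input_dim = 100L, output_dim = 86L, seed = 0L) {
  model_config(input_dim = input_dim, hidden_layers = 9L, hidden_units = 128L,
               output_dim = output_dim, batch_norm = TRUE,
               learning_rate = 0.001, batch_size = 256L, epochs = 20L,
               seed = seed)
}

#' Run the full synthetic study
#'
#' Generates the scenario, featurizes all structures (fingerprints against
#' the registry panel, PCA-reduced profiles), trains the classifier on a
#' 60/20/20 split of the gold standard, predicts DDIs over all drug pairs
#' and DFIs over all food-drug pairs at the doubled screening threshold,
#' validates DFIs structurally, screens the cohort, and produces the
#' mechanism, substitution and food-network reports.
#'
#' @param cfg A [scenario_config()].
#' @param pcfg A [pipeline_config()].
#' @param net_cfg A `ddi_model_config`; defaults to [desk_model_config()]
#'   seeded from `cfg$seed`.
#' @param verbose Print progress. Default `FALSE`.
#' @return A list of class `ddi_study` with the scenario, features, model,
#'   history, accuracy metrics, prediction sets, cohort report and the three
#'   clinical reports.
#' @export
run_scenario <- function(cfg = scenario_config(), pcfg = pipeline_config(),
                         net_cfg = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("generating scenario")
  scn <- gen_scenario(cfg)
  registry <- scn$registry

  say("fingerprinting and profiling")
  drugs <- registry[registry$has_structure, ]
  fps <- fingerprint_set(stats::setNames(drugs$canonical_smiles, drugs$drug_id),
                         radius = pcfg$radius, n_bits = pcfg$n_bits)
  panel_id <- "registry"
  profiles <- similarity_profiles(fps, fps, panel_id = panel_id)

  gold <- scn$gold
  gold_drugs <- unique(c(gold$subject_id, gold$object_id))
  projection <- fit_projection(profiles[gold_drugs, , drop = FALSE],
                               k = pcfg$k, panel_id = panel_id,
                               n_bits = pcfg$n_bits, radius = pcfg$radius)
  red <- project_profiles(projection, profiles)
  rownames(red) <- rownames(profiles)

  say("training on the gold-standard split")
  split <- split_dataset(gold, seed = cfg$seed)
  feat <- function(rec) {
    cbind(red[rec$subject_id, , drop = FALSE],
          red[rec$object_id, , drop = FALSE])
  }
  if (is.null(net_cfg)) {
    net_cfg <- desk_model_config(input_dim = 2L * pcfg$k,
                                 output_dim = nrow(scn$templates),
                                 seed = cfg$seed)
  }
  fit <- train_model(feat(split$train), split$train$type_id, net_cfg,
                     feat(split$validation), split$validation$type_id)
  model <- fit$model
  test_accuracy <- categorical_accuracy(model, feat(split$test),
                                        split$test$type_id)

  say("gold-recovery check at the default threshold")
  P_fwd <- pair_activations(gold$subject_id, gold$object_id, model,
                            projection, profiles)
  P_rev <- pair_activations(gold$object_id, gold$subject_id, model,
                            projection, profiles)
  fired <- P_fwd[cbind(seq_len(nrow(gold)), gold$type_id)] >=
    pcfg$threshold_default |
    P_rev[cbind(seq_len(nrow(gold)), gold$type_id)] >= pcfg$threshold_default
  gold_recovery <- mean(fired)

  say("predicting all drug pairs")
  pred_ddi <- predict_all_pairs(drugs$drug_id, model, projection, profiles,
                                threshold = pcfg$threshold_screen)
  pred_ddi$records <- label_known(pred_ddi$records, gold)

  say("predicting and validating drug-food interactions")
  food <- scn$food$compounds[scn$food$compounds$has_structure, ]
  food_fps <- fingerprint_set(
    stats::setNames(food$canonical_smiles, food$compound_id),
    radius = pcfg$radius, n_bits = pcfg$n_bits)
  food_profiles <- similarity_profiles(food_fps, fps, panel_id = panel_id)
  all_profiles <- rbind(profiles, food_profiles)
  pred_dfi <- predict_dfis(food$compound_id, drugs$drug_id, model, projection,
                           all_profiles, threshold = pcfg$threshold_screen)
  approved <- drugs$drug_id[drugs$drug_id %in%
                              registry$drug_id[registry$approved]]
  dice_fd <- dice_matrix(food_fps, fps[approved])
  valid <- validate_dfi(pred_dfi$records, dice_fd, gold, food$compound_id,
                        dice_min = pcfg$dice_min)
  pred_dfi$records_all <- pred_dfi$records
  pred_dfi$records <- pred_dfi$records[valid, , drop = FALSE]

  say("screening the cohort")
  report <- screen_cohort(scn$plans, gold, pred_ddi, registry)
  cpairs <- cohort_pairs(scn$plans,
                         predictable = registry$drug_id[registry$has_structure])

  say("mechanism candidates")
  mechanisms <- find_mechanism_candidates(cpairs, gold, pred_ddi)

  say("substitution analysis")
  substitutions <- substitution_analysis(
    cpairs, pred_ddi, registry, model, projection, profiles, gold = gold,
    safety_threshold = pcfg$safety_threshold)

  say("food-interaction network")
  conc <- filter_concentration_dfis(pred_dfi$records, food$compound_id)
  network <- build_network(conc, scn$food$contents, k = pcfg$top_k_sources,
                           names = c(stats::setNames(registry$name,
                                                     registry$drug_id),
                                     stats::setNames(food$name,
                                                     food$compound_id)))

  structure(list(
    scenario = scn, pipeline_config = pcfg, net_config = net_cfg,
    fingerprints = fps, profiles = profiles, food_profiles = food_profiles,
    projection = projection, split = split, model = model,
    history = fit$history, test_accuracy = test_accuracy,
    gold_recovery = gold_recovery, pred_ddi = pred_ddi, pred_dfi = pred_dfi,
    cohort_report = report, cohort_pairs = cpairs, mechanisms = mechanisms,
    substitutions = substitutions, concentration_dfis = conc,
    network = network),
    class = "ddi_study")
}

#' @export
print.ddi_study <- function(x, ...) {
  cat("Synthetic interaction-screening study\n")
  cat(sprintf("  drugs: %d, gold DDIs: %d, patients: %d, food compounds: %d\n",
              nrow(x$scenario$registry), nrow(x$scenario$gold),
              nrow(x$scenario$plans), nrow(x$scenario$food$compounds)))
  cat(sprintf("  held-out categorical accuracy: %.3f\n", x$test_accuracy))
  cat(sprintf("  gold recovery at %.2f: %.3f\n",
              x$pipeline_config$threshold_default, x$gold_recovery))
  cat(sprintf("  predicted DDIs (>= %.2f): %d over %d pairs\n",
              x$pred_ddi$threshold, nrow(x$pred_ddi$records),
              x$pred_ddi$n_unordered_pairs))
  cat(sprintf("  validated DFIs: %d\n", nrow(x$pred_dfi$records)))
  cat(sprintf("  cohort DDI prevalence: %.1f%% (gold) / %.1f%% (predicted)\n",
              100 * x$cohort_report$prevalence_gold,
              100 * x$cohort_report$prevalence_pred))
  invisible(x)
}
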