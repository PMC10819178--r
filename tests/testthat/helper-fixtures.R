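# Shared fixtures, built in code. The small trained study is expensive
# (~15 s) and is memoized across test files.

.fixture_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- scenario_config(n_drugs = 130, n_patients = 80,
                           n_food_compounds = 30, n_food_sources = 20,
                           seed = 7)
    # smaller minibatches than the desk default keep the step count adequate
    # at this reduced training-set size
    net <- model_config(input_dim = 100, hidden_layers = 9,
                        hidden_units = 128, output_dim = 86,
                        batch_size = 64, epochs = 20, seed = 7)
    .fixture_env$study <- suppressWarnings(run_scenario(cfg, net_cfg = net))
  }
  .fixture_env$study
}

# minimal registry data frame in the raw file schema
toy_registry_df <- function() {
  data.frame(
    id = c("A", "B", "C", "D", "E", "F"),
    name = c("Alphanol", "Betanol", "Gammanol", "Deltanol", "Epsilonol",
             "Zetanol"),
    smiles = c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "not_a_smiles", "CCCO"),
    approved = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    targets = c("T1:inhibitor", "T1:inhibitor", "T1:agonist", "T2:agonist",
                "T3:inhibitor", ""),
    category = c("non_dmd", "non_dmd", "dmd", "non_dmd", "non_dmd", "btki"),
    stringsAsFactors = FALSE)
}

toy_records <- function(subject, object, type, score = 0.95,
                        provenance = "predicted") {
  tibble::tibble(subject_id = subject, object_id = object,
                 type_id = as.integer(type), score = score,
                 provenance = provenance)
}

random_fp <- function(n_on, n_bits = 64L) {
  structure(list(bits = sort(sample.int(n_bits, n_on) - 1L),
                 n_bits = as.integer(n_bits), radius = 2L),
            class = "ddi_fingerprint")
}

# SMILES the generator grammar can produce, for canonicalization properties
sample_valid_smiles <- function(n, seed = 1) {
  withr::with_seed(seed, {
    scaf <- c("c1ccc(%s)cc1", "C1CCN(%s)CC1", "C1CCC(%s)CC1", "c1cc(%s)ccn1",
              "O=C(O)c1ccc(%s)cc1", "O1CCN(%s)CC1", "c1cc(%s)oc1")
    sub <- c("C", "CC", "CCO", "CO", "CN", "Cl", "F", "C(=O)O", "C(C)C",
             "CCN", "COC", "CC#N")
    sprintf(sample(scaf, n, TRUE), sample(sub, n, TRUE))
  })
}
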