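Package: ddiscreen
Title: Structure-Based Prediction and Clinical Screening of Drug-Drug and
    Drug-Food Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-label classifier of 86 drug-drug interaction (DDI) types
    from chemical-structure similarity, in the style of DeepDDI, together with
    its downstream clinical analyses. Drugs are featurized as Morgan circular
    fingerprints compared against a fixed reference panel by Dice similarity,
    reduced by principal component analysis, and pairs of reduced profiles are
    classified by a deep feed-forward network with sigmoid outputs. The package
    screens patient medication plans for pairwise DDIs, infers mechanism
    candidates for adverse-effect interactions, suggests target-matched drug
    substitutions that avoid critical interaction types, validates predicted
    drug-food interactions by structural similarity to approved drugs, and
    exports food-source/compound/drug concentration-interaction networks. A
    synthetic-data generator provides desk-scale drug libraries, gold-standard
    interaction sets, patient cohorts and food-composition tables with the
    statistical structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    dplyr,
    igraph,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
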