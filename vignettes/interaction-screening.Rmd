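---
title: "Structure-based interaction screening: model, data generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based interaction screening: model, data generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ddiscreen` implements a multi-label classifier of 86 drug-drug interaction
(DDI) types from chemical structure alone, in the DeepDDI family, plus the
downstream clinical analyses that make such a classifier useful at the
bedside: medication-plan screening, mechanism inference for adverse-effect
interactions, target-matched drug substitution, and drug-food interaction
(DFI) networks.

The featurization chain is:

1. **Morgan circular fingerprints** (radius 2, 2048 hashed bits). Atom
   environments of radius 0, 1 and 2 are encoded by iteratively hashing each
   atom's invariant together with the sorted (bond order, neighbour
   invariant) list; every environment identifier is hashed into the bit
   space. The initial atom invariant covers atomic number, heavy-atom
   degree, implicit hydrogen count, formal charge, ring membership and total
   bond order, so the bit set is invariant under atom renumbering of the
   input — a property the test suite checks against RDKit-randomized SMILES
   orderings. SMILES parsing and canonicalization go through OpenBabel
   (ChemmineOB); the fingerprint itself is authored here because no
   installed R package computes Morgan fingerprints.
2. **Structural similarity profiles.** Each compound is compared against a
   fixed, ordered reference panel by the Dice coefficient
   `2|A∩B| / (|A| + |B|)` on fingerprint bits. The reference analysis used a
   2159-drug panel; in synthetic runs the panel is the generated registry
   itself, and the panel identity and order are persisted with the
   projection model.
3. **PCA reduction to k = 50.** The projection is fitted on the similarity
   profiles of all gold-standard drugs (features precede the data split in
   the workflow), without whitening; component signs are fixed by making
   each component's largest-magnitude loading positive so refits are
   bit-reproducible. An ordered drug pair is represented by the
   concatenation of its two reduced profiles (length 100, subject first).
4. **The classifier**: nine hidden layers of 2048 rectified-linear units
   with batch normalization (after the linear transform, before the
   activation) and 86 sigmoid outputs — 33,990,742 trainable parameters
   (33,953,878 if the batch-norm scale/shift pairs are excluded; both round
   to 34 million). Training minimizes per-output binary cross-entropy with
   Adam at learning rate 0.001, batch size 1024, for a fixed 20 epochs with
   no early stopping and no class reweighting. Gold labels are one type per
   pair, consumed as one-hot multi-label targets; the only accuracy metric
   is categorical accuracy (argmax vs gold, ties to the lowest type ID).
   The network, its gradients and the Adam update are written in plain R
   matrix code and are finite-difference-checked in the test suite.

Two activation thresholds matter downstream: 0.47 (the default at which a
type counts as predicted, used for the gold-recovery check and the
substitution safety rule) and 0.94 (the doubled threshold that defines the
high-confidence screening predictions). Predictions are evaluated for both
orderings of every unordered pair; a type fired in both orderings is
reported once, for the higher-scoring ordering, so cohort tallies do not
double-count.

## Clinical post-processing

* **Cohort screening** counts, per patient, the `C(m, 2)` unordered pairs
  of predictable co-medications ("counting with repetitions" across
  patients: the same pair in several plans counts once per patient) and the
  gold and predicted interactions among them. A pair with two predicted
  types contributes two DDIs but one combination.
* **Mechanism inference**: most adverse-effect interactions are recorded as
  type 26 ("risk or severity of adverse effects can be increased") with
  unknown mechanism. Pairs that are (1) taken together by some patient,
  (2) gold-labelled 26 and predicted 26, and (3) co-predicted with at least
  one other type are reported with those other types as mechanism
  candidates, ordered by score.
* **Substitution**: for a pair flagged with a predicted critical type (the
  14 types 18–23 and 25–32), each drug's target-matched alternatives
  (approved drugs with an identical target-action set; a superset-match
  relaxation is available but off by default) are evaluated as replacement
  partners. A suggestion is accepted only if every critical-type activation
  of the new pair, in both orderings, stays below 0.47 — both orderings,
  because critical sentences are directional — and, as a conservative
  addition, the gold standard contains no critical record for the new pair.
* **DFI analysis**: food compounds run through the same 86-type head. A
  predicted DFI survives only if some approved drug is structurally similar
  to the food compound (Dice ≥ 0.75, boundary inclusive) and has a
  same-type gold record. The concentration network keeps the eight types
  describing absorption (1/2), bioavailability (4/5), metabolism (6/7) and
  serum concentration (9/10) with the food compound as sentence subject,
  labels each edge as a decrease (1, 4, 7, 9) or increase (2, 5, 6, 10) of
  drug concentration, and attaches each compound's top 10 food sources
  ranked by maximum reported content (maximum rather than mean: robust to
  duplicate content rows; a mean option is exposed).

## What the synthetic generator emulates

The real inputs — a licensed drug-database dump, a food-composition
database and a private patient cohort — cannot ship with the package, so
`scenario_config()` + `gen_scenario()` build a desk-scale stand-in with the
statistical structure the analyses assume:

* **Drugs** are unique scaffold × substituent combinations from a grammar of
  12 ring systems and 25 substituents, all yielding valid SMILES. The
  scaffold is the interaction-determining motif; the substituent acts as the
  pharmacophore: drugs sharing a substituent class share their target-action
  set, which guarantees substitution candidates exist across scaffolds.
  Six drugs of one class are disease-modifying drugs (DMDs), five of
  another are investigational BTK inhibitors with no gold records of their
  own (all their interactions are model-predicted).
* **Gold labels** are a deterministic function of the two drugs' motif
  classes through a fixed ordered rule table, so structurally similar drugs
  have similar interaction patterns — the working assumption of the
  classifier — and exactly one type is recorded per unordered pair. Most
  rule cells are symmetric; designated cells carry the critical and the
  eight concentration-altering types. Four cells are *directional*: the
  forward ordering carries type 26 and the reverse a mechanistic type, with
  the gold subject chosen by the parity of the lower-scaffold drug's
  substituent class. Both orderings therefore appear in training (across
  different pairs), the model learns both confidently, and evaluating both
  orderings at prediction time yields genuine multi-type pairs — the
  pattern the mechanism-inference analysis needs. Labels remain
  deterministic in the motif sets.
* **Gold density** defaults to 0.23 of eligible pairs. This was calibrated
  once so that roughly 70–85% of cohort patients carry at least one
  gold-standard interaction (the generator's design bracket); it also gives
  each ordered rule cell enough training pairs for confident predictions.
* **Cohorts** draw per-patient medication counts from a truncated negative
  binomial on [0, 19] whose parameters are moment-matched numerically to
  mean 5.3 and SD 3.3 (overdispersed counts with a hard range); 62% of
  patients receive one DMD, and disease-course labels follow a fixed
  CIS/RRMS/SPMS/PPMS mixture.
* **Food compounds**: 20% are structural analogs of approved drugs (so the
  Dice ≥ 0.75 validation path fires); the rest come from a food-like
  grammar (sugars, fatty acids, phenolics, amino acids, terpenes) that stays
  structurally distant from the drug scaffolds. Content amounts are
  log-normal and positive, and one compound always has ≥ 11 sources so the
  top-10 truncation is exercised.

What passing tests on this generator do **not** show: real drug chemistry is
far more diverse than a 12-scaffold grammar, real interaction labels are
noisy, incomplete and imbalanced rather than a deterministic function of
structure, and the reference accuracy on the licensed corpus
(92.14% on ~209k held-out interactions) is not desk-reproducible. The
synthetic end-to-end accuracy (~1.0 held-out at the default scenario) is
the stand-in statement "the architecture can learn structure-determined
interaction patterns", not a claim about real data.

## Numerical choices and degenerate inputs

* Hashing is 32-bit FNV-1a implemented on doubles (R integers are signed
  32-bit); bit collisions are accepted as in any hashed fingerprint.
* Batch normalization uses biased batch variance, epsilon 1e-5 and running
  statistics with momentum 0.9; training batches of size 1 are skipped
  (batch statistics undefined).
* Sigmoid outputs are clamped to [1e-7, 1 - 1e-7] inside the loss.
* Dataset splits give `floor(N * fraction)` records to validation and test
  and the remainder to training (a 60/20/20 split of 1,046,705 records is
  628,023/209,341/209,341); splits are seed-deterministic.
* Argmax ties resolve to the lowest type ID; food-source ranking ties break
  lexicographically by source name.
* Unparseable SMILES: corpus loaders retain the record but flag it
  structure-less and exclude it from prediction (the filter drops gold
  records involving such drugs, with per-reason counts); direct API calls
  raise errors naming the offending input. Batch canonicalization falls
  back to per-molecule calls when OpenBabel truncates batch output at a
  malformed entry.
* Projection models and trained networks persist to text (CSV with a JSON
  header; JSON weights at full double precision) and reload
  bit-compatibly.

## Problem sizes

The shipped default scenario uses 300 drugs (~10,000 gold interactions),
627 patients, 150 food compounds and 80 sources; the full study —
generation, featurization, 20 training epochs, ~45,000 drug pairs and
~45,000 food-drug pairs both evaluated in two orderings, screening and all
three reports — runs in about four minutes on one CPU. The test suite uses
a 130-drug fixture for the integration checks and pure-logic fixtures
elsewhere. The desk classifier keeps the reference depth (nine hidden
layers, batch norm, 20 epochs) at width 128; width is the one deliberate
reduction, and `model_config()` restores the full 2048-unit architecture.

## Known limitations

Severity grading, dose, timing and route are outside the data model, as are
drug-gene and higher-order interactions; alternative-drug matching uses
declared targets only (no potency or indication awareness); the DFI
orientation convention relies on sentence-subject semantics of the
template catalogue; and the synthetic generator's simplifications listed
above bound what the green suite can claim about real corpora.
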