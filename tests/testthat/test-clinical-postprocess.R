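# Mechanism inference for adverse-effect DDIs and substitution suggestions.

test_that("mechanism candidates satisfy exactly the three printed conditions", {
  pairs <- tibble::tibble(drug_a = c("A", "A", "B"), drug_b = c("B", "C", "C"))
  gold <- toy_records(c("A", "A", "D"), c("B", "C", "E"), c(26, 15, 26),
                      provenance = "gold")
  pred <- toy_records(c("A", "A", "A", "A", "D", "D"),
                      c("B", "B", "C", "C", "E", "E"),
                      c(26, 6, 26, 6, 26, 9),
                      score = c(0.99, 0.95, 0.99, 0.97, 0.99, 0.98))
  out <- find_mechanism_candidates(pairs, gold, pred)
  # A-B: cohort pair, gold 26, predicted {26, 6} -> mechanism type 6
  expect_equal(nrow(out), 1)
  expect_equal(out$drug_a, "A")
  expect_equal(out$drug_b, "B")
  expect_equal(out$mechanism_type, 6L)
  # A-C excluded (gold type 15, not 26); D-E excluded (not a cohort pair)
  # a pair with gold 26 but predicted {26} only is excluded
  pred2 <- toy_records("A", "B", 26)
  expect_equal(nrow(find_mechanism_candidates(pairs, gold, pred2)), 0)
  # a pair with gold 26 but 26 not among predictions is excluded
  pred3 <- toy_records("A", "B", 6)
  expect_equal(nrow(find_mechanism_candidates(pairs, gold, pred3)), 0)
})

test_that("mechanism candidates equal a brute-force filter on random fixtures", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      drugs <- paste0("d", 1:8)
      pr <- t(utils::combn(drugs, 2))
      cohort <- pr[sample(nrow(pr), 15), ]
      pairs <- tibble::tibble(drug_a = cohort[, 1], drug_b = cohort[, 2])
      gidx <- sample(nrow(pr), 12)
      gold <- toy_records(pr[gidx, 1], pr[gidx, 2],
                          sample(c(26, 15, 6), 12, TRUE), provenance = "gold")
      pidx <- sample(nrow(pr), 20, replace = TRUE)
      pred <- toy_records(pr[pidx, 1], pr[pidx, 2],
                          sample(c(26, 6, 9, 15), 20, TRUE),
                          score = runif(20, 0.94, 1))
      pred <- pred[!duplicated(pred[, c("subject_id", "object_id", "type_id")]), ]
      got <- find_mechanism_candidates(pairs, gold, pred)
      # oracle: direct three-condition scan over every unordered pair
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      want <- 0L
      for (r in seq_len(nrow(pr))) {
        k <- key(pr[r, 1], pr[r, 2])
        in_cohort <- k %in% key(pairs$drug_a, pairs$drug_b)
        g26 <- any(key(gold$subject_id, gold$object_id) == k &
                     gold$type_id == 26)
        ptypes <- unique(pred$type_id[key(pred$subject_id, pred$object_id) == k])
        if (in_cohort && g26 && 26 %in% ptypes && length(setdiff(ptypes, 26)))
          want <- want + length(setdiff(ptypes, 26))
      }
      expect_equal(nrow(got), want)
      if (nrow(got) > 0) {
        # scores are non-increasing within each pair
        by_pair <- split(got$score, paste(got$drug_a, got$drug_b))
        expect_true(all(vapply(by_pair, function(s) all(diff(s) <= 0), TRUE)))
      }
    }
  })
})

test_that("alternatives require exact target-action set equality among approved drugs", {
  reg <- load_registry(data.frame(
    id = c("A", "B", "C", "D", "E"),
    name = paste0("n", 1:5),
    smiles = c("CCO", "CCN", "CCS", "CCC", "CCCC"),
    approved = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    targets = c("T1:inhibitor", "T1:inhibitor", "T1:agonist", "T1:inhibitor",
                "T1:inhibitor;T2:agonist"),
    category = "non_dmd"))
  expect_equal(find_alternatives("A", reg), "B")  # C differs, D unapproved
  expect_false("A" %in% find_alternatives("A", reg))
  # superset matching admits E
  expect_equal(find_alternatives("A", reg, superset_match = TRUE), c("B", "E"))
  # no other drug shares the set -> empty
  expect_length(find_alternatives("C", reg), 0)
  reg2 <- reg
  reg2$targets[1] <- ""
  expect_warning(out <- find_alternatives("A", reg2), "no target")
  expect_length(out, 0)
})

test_that("substitution suggestions equal an exhaustive search and pass re-audit", {
  st <- small_study()
  subs <- st$substitutions
  skip_if(is.null(subs$suggestions) || nrow(subs$flagged) == 0,
          "no flagged pairs in the small study")
  reg <- st$scenario$registry
  # brute-force oracle over the first few flagged pairs
  n_check <- min(3, nrow(subs$flagged))
  for (i in seq_len(n_check)) {
    a <- subs$flagged$drug_a[i]; b <- subs$flagged$drug_b[i]
    got <- suggest_substitutions(a, b, reg, st$model, st$projection,
                                 st$profiles, gold = st$scenario$gold)
    want <- list()
    gold_crit <- st$scenario$gold[st$scenario$gold$type_id %in% critical_types(), ]
    gck <- paste(pmin(gold_crit$subject_id, gold_crit$object_id),
                 pmax(gold_crit$subject_id, gold_crit$object_id))
    for (replaced in c(a, b)) {
      partner <- setdiff(c(a, b), replaced)
      for (alt in suppressWarnings(find_alternatives(replaced, reg))) {
        if (alt %in% c(a, b)) next
        if (!alt %in% rownames(st$profiles)) next
        P <- pair_activations(c(alt, partner), c(partner, alt), st$model,
                              st$projection, st$profiles)
        mca <- max(P[, critical_types()])
        veto <- paste(min(alt, partner), max(alt, partner)) %in% gck
        if (mca < 0.47 && !veto) {
          want[[length(want) + 1]] <- c(replaced, alt, sprintf("%.10f", mca))
        }
      }
    }
    expect_equal(nrow(got), length(want))
    if (nrow(got) > 0) {
      expect_equal(got$alternative, vapply(want, `[`, "", 2))
      # re-audit: every accepted suggestion stays below the safety threshold
      for (j in seq_len(nrow(got))) {
        expect_lt(max_critical_activation(got$alternative[j], got$partner[j],
                                          st$model, st$projection,
                                          st$profiles), 0.47)
      }
    }
  }
  # the analysis-level audit: all emitted suggestions satisfy the predicate
  if (!is.null(subs$suggestions) && nrow(subs$suggestions) > 0) {
    expect_true(all(subs$suggestions$max_critical_activation < 0.47))
  }
})

test_that("borderline activations are rejected at and above the safety threshold", {
  st <- small_study()
  subs <- st$substitutions
  skip_if(is.null(subs$suggestions) || nrow(subs$flagged) == 0,
          "no flagged pairs in the small study")
  a <- subs$flagged$drug_a[1]; b <- subs$flagged$drug_b[1]
  reg <- st$scenario$registry
  # a tiny safety threshold rejects everything a permissive one accepts
  strict <- suggest_substitutions(a, b, reg, st$model, st$projection,
                                  st$profiles, safety_threshold = 1e-6)
  loose <- suggest_substitutions(a, b, reg, st$model, st$projection,
                                 st$profiles, safety_threshold = 0.999)
  expect_equal(nrow(strict), 0)
  expect_true(all(suggest_substitutions(a, b, reg, st$model, st$projection,
                                        st$profiles)$alternative %in%
                    loose$alternative))
})

test_that("adding alternatives never makes a preventable pair unpreventable", {
  st <- small_study()
  subs <- st$substitutions
  skip_if(is.null(subs$suggestions) || is.null(subs$suggestions) ||
            nrow(subs$suggestions) == 0, "no suggestions in the small study")
  a <- subs$suggestions$drug_a[1]; b <- subs$suggestions$drug_b[1]
  reg <- st$scenario$registry
  # restricting approvals shrinks the alternatives list; the full registry
  # must yield a superset of suggestions
  reg_small <- reg
  keep <- unique(c(a, b, subs$suggestions$alternative[1]))
  reg_small$approved <- reg_small$approved & (reg_small$drug_id %in% keep)
  few <- suggest_substitutions(a, b, reg_small, st$model, st$projection,
                               st$profiles)
  all_sugg <- suggest_substitutions(a, b, reg, st$model, st$projection,
                                    st$profiles)
  expect_true(all(few$alternative %in% all_sugg$alternative))
  expect_gte(nrow(all_sugg), nrow(few))
})
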