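# Structure featurization: canonicalization, Morgan fingerprints, Dice
# similarity, profiles and the PCA projection.

test_that("canonicalization maps equivalent notations to one form and is idempotent", {
  expect_identical(canonical_smiles("OCC"), canonical_smiles("CCO"))
  expect_identical(canonicalize_structure("OC(=O)c1ccccc1")$smiles,
                   canonicalize_structure("c1ccccc1C(=O)O")$smiles)
  smis <- unique(sample_valid_smiles(100, seed = 4))
  can1 <- canonical_smiles(smis)
  expect_false(anyNA(can1))
  # double application is the identity on canonical forms
  expect_identical(canonical_smiles(can1), can1)
})

test_that("malformed SMILES are rejected with a structured error", {
  expect_error(canonicalize_structure("C1CC"), "unparseable SMILES.*C1CC")
  expect_error(canonicalize_structure("not_a_smiles"), "unparseable")
  expect_identical(canonical_smiles(c("CCO", "C1CC", "CCN"))[2], NA_character_)
})

test_that("fingerprints are deterministic and atom-order invariant", {
  mol <- canonicalize_structure("c1ccc2[nH]c(CCN)cc2c1")
  expect_identical(morgan_fingerprint(mol)$bits, morgan_fingerprint(mol)$bits)
  # equivalent SMILES written with different atom orders parse to permuted
  # connection tables; the bit sets must agree (no canonicalization applied)
  variants <- list(
    c("CCO", "OCC"),
    c("c1ccccc1C(=O)O", "OC(=O)c1ccccc1", "C(c1ccccc1)(=O)O"),
    c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"),
    c("C1CCN(CC1)CCO", "OCCN1CCCCC1"))
  for (v in variants) {
    sdfs <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(v, seq_along(v))))
    fps <- lapply(seq_along(v), function(i) morgan_fingerprint(sdfs[[i]]))
    for (i in seq_along(fps)[-1]) {
      expect_identical(fps[[i]]$bits, fps[[1]]$bits, label = v[i])
    }
  }
})

test_that("fingerprint bits are invariant under RDKit-randomized atom orderings", {
  smis <- unique(sample_valid_smiles(20, seed = 9))
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "for line in sys.stdin:",
    "    m = Chem.MolFromSmiles(line.strip())",
    "    out = [Chem.MolToSmiles(m, canonical=False, doRandom=True) for _ in range(3)]",
    "    print('\\t'.join(out))"), script)
  res <- suppressWarnings(
    system2("python", script, stdout = TRUE, stderr = FALSE,
            input = paste(smis, collapse = "\n")))
  skip_if(length(res) != length(smis), "python/rdkit oracle unavailable")
  for (i in seq_along(smis)) {
    all_forms <- c(smis[i], strsplit(res[i], "\t", fixed = TRUE)[[1]])
    sdfs <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(all_forms, seq_along(all_forms))))
    fps <- lapply(seq_along(all_forms),
                  function(j) morgan_fingerprint(sdfs[[j]]))
    for (j in seq_along(fps)[-1]) {
      expect_identical(fps[[j]]$bits, fps[[1]]$bits, label = smis[i])
    }
  }
})

test_that("environment radii nest: radius-0 bits are a subset of radius-2 bits", {
  for (s in sample_valid_smiles(10, seed = 2)) {
    mol <- canonicalize_structure(s)
    f0 <- morgan_fingerprint(mol, radius = 0)
    f2 <- morgan_fingerprint(mol, radius = 2)
    expect_true(all(f0$bits %in% f2$bits))
    expect_lte(length(f0$bits), length(f2$bits))
  }
})

test_that("Dice similarity matches hand set-arithmetic and its axioms", {
  fa <- structure(list(bits = c(1L, 2L, 3L), n_bits = 16L, radius = 2L),
                  class = "ddi_fingerprint")
  fb <- structure(list(bits = c(2L, 3L, 4L), n_bits = 16L, radius = 2L),
                  class = "ddi_fingerprint")
  fc <- structure(list(bits = c(8L, 9L), n_bits = 16L, radius = 2L),
                  class = "ddi_fingerprint")
  expect_equal(dice_similarity(fa, fb), 2 * 2 / (3 + 3))
  expect_equal(dice_similarity(fa, fa), 1.0)
  expect_equal(dice_similarity(fa, fc), 0.0)
  wrong <- structure(list(bits = 0L, n_bits = 32L, radius = 2L),
                     class = "ddi_fingerprint")
  expect_error(dice_similarity(fa, wrong), "n_bits")
  withr::with_seed(5, {
    for (i in 1:25) {
      a <- random_fp(sample(1:20, 1))
      b <- random_fp(sample(1:20, 1))
      expect_equal(dice_similarity(a, b), dice_similarity(b, a))
      expect_gte(dice_similarity(a, b), 0)
      expect_lte(dice_similarity(a, b), 1)
      expect_equal(dice_similarity(a, a), 1)
    }
  })
})

test_that("similarity profiles equal the brute-force pairwise loop", {
  smis <- c("CCO", "CCN", "c1ccccc1", "CC(=O)O", "c1ccncc1", "C1CCCCC1",
            "CCOC", "CCS", "c1ccc(Cl)cc1", "OCC(O)CO")
  fps <- fingerprint_set(stats::setNames(smis, paste0("d", 1:10)))
  prof <- similarity_profile(fps[["d3"]], fps, panel_id = "p10")
  expect_length(prof, 10)
  expect_equal(unname(prof["d3"]), 1.0)
  brute <- vapply(fps, function(p) {
    2 * length(intersect(fps[["d3"]]$bits, p$bits)) /
      (length(fps[["d3"]]$bits) + length(p$bits))
  }, numeric(1))
  expect_equal(as.numeric(prof), as.numeric(brute))
  expect_true(all(prof >= 0 & prof <= 1))
  # matrix route agrees with the scalar route
  pm <- similarity_profiles(fps, fps, panel_id = "p10")
  expect_equal(as.numeric(pm["d3", ]), as.numeric(prof))
  expect_equal(unname(diag(pm)), rep(1, 10))
  # a 7-member panel yields length-7 profiles
  expect_length(similarity_profile(fps[[1]], fps[1:7]), 7)
})

test_that("projection recovers exactly planar data and orders variance", {
  withr::with_seed(8, {
    basis <- qr.Q(qr(matrix(rnorm(15), 5, 3)))[, 1:2]
    scores <- matrix(rnorm(40), 20, 2) %*% diag(c(3, 1))
    X <- scores %*% t(basis) + matrix(1, 20, 1) %*% rnorm(5)
  })
  m <- fit_projection(X, k = 2)
  red <- project_profiles(m, X)
  recon <- sweep(red %*% m$components, 2, m$mean, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_true(all(diff(m$explained_var) <= 1e-12))
  expect_lt(max(abs(m$components %*% t(m$components) - diag(2))), 1e-8)
  expect_lt(max(abs(project_profiles(m, m$mean))), 1e-10)
  expect_error(fit_projection(X, k = 6), "exceeds")
})

test_that("increasing k never increases reconstruction error on the fitting set", {
  withr::with_seed(11, X <- matrix(runif(200), 20, 10))
  errs <- vapply(1:5, function(k) {
    m <- fit_projection(X, k = k)
    red <- project_profiles(m, X)
    recon <- sweep(red %*% m$components, 2, m$mean, `+`)
    sum((recon - X)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("pair features concatenate projections in order", {
  withr::with_seed(3, X <- matrix(runif(50), 10, 5))
  rownames(X) <- paste0("d", 1:10)
  m <- fit_projection(X, k = 2)
  f_ab <- pair_feature("d1", "d2", m, X)
  f_ba <- pair_feature("d2", "d1", m, X)
  expect_length(f_ab, 4)
  expect_equal(unname(f_ab[1:2]), unname(f_ba[3:4]))
  expect_equal(unname(f_ab[3:4]), unname(f_ba[1:2]))
  # matrix-product oracle
  manual <- c((X["d1", ] - m$mean) %*% t(m$components),
              (X["d2", ] - m$mean) %*% t(m$components))
  expect_equal(unname(as.numeric(f_ab)), unname(manual))
  expect_error(pair_feature("d1", "nope", m, X), "nope")
  # default k gives the length-100 classifier input
  big <- matrix(runif(60 * 55), 60, 55)
  rownames(big) <- paste0("x", 1:60)
  m50 <- fit_projection(big, k = 50)
  expect_length(pair_feature("x1", "x2", m50, big), 100)
})

test_that("the SMILES-to-feature chain is deterministic across runs", {
  run_chain <- function() {
    smis <- stats::setNames(sample_valid_smiles(12, seed = 21), paste0("d", 1:12))
    fps <- fingerprint_set(smis)
    prof <- similarity_profiles(fps, fps)
    m <- fit_projection(prof, k = 4)
    pair_feature("d1", "d2", m, prof)
  }
  expect_identical(run_chain(), run_chain())
})

test_that("projection models persist to text and reload bit-compatibly", {
  withr::with_seed(13, X <- matrix(runif(80), 16, 5))
  colnames(X) <- paste0("ref", 1:5)
  m <- fit_projection(X, k = 3, panel_id = "toy-panel", n_bits = 512L,
                      radius = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_projection(m, path)
  m2 <- read_projection(path)
  expect_identical(unname(m2$components), unname(m$components))
  expect_identical(unname(m2$mean), unname(m$mean))
  expect_identical(m2$k, m$k)
  expect_identical(m2$panel_id, "toy-panel")
  expect_identical(m2$n_bits, 512L)
})
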