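# Structure featurization: canonical SMILES, Morgan circular fingerprints,
# Dice similarity profiles against a reference panel, and PCA-reduced pair
# feature vectors for the classifier.

# ---- 32-bit hashing on doubles (R integers cannot hold unsigned 32-bit) ----

.xor32 <- function(a, b) {
  bitwXor(as.integer(a %% 65536), as.integer(b %% 65536)) +
    65536 * bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
}

.mul32 <- function(a, b) {
  # (a * b) mod 2^32 without exceeding double precision
  ((a %% 65536) * b + (((a %/% 65536) * b) %% 65536) * 65536) %% 4294967296
}

# FNV-1a over a vector of non-negative integers
.hash32 <- function(ints) {
  h <- 2166136261
  for (x in ints) {
    h <- .xor32(h, x %% 4294967296)
    h <- .mul32(h, 16777619)
  }
  h
}

# ---- canonicalization -------------------------------------------------------

.canon_one <- function(smiles) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else strsplit(out, "[ \t]")[[1]][1]
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form, so that two notations of the
#' same molecule yield identical text. Unparseable inputs map to `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO"))  # identical canonical forms
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  # Batch conversion is much faster, but OpenBabel truncates its output at the
  # first unparseable input; fall back to per-molecule calls in that case.
  batch <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste(smiles[ok], collapse = "\n")),
    error = function(e) "")
  lines <- strsplit(batch, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  if (length(lines) == sum(ok) && all(nzchar(lines))) {
    out[ok] <- vapply(strsplit(lines, "[ \t]"), `[`, "", 1)
  } else {
    out[ok] <- vapply(smiles[ok], .canon_one, "", USE.NAMES = FALSE)
  }
  out
}

#' Parse and canonicalize a single structure
#'
#' @param smiles A single SMILES string.
#' @return A list of class `ddi_molecule` with elements `smiles` (canonical
#'   form) and `sdf` (a `ChemmineR` SDF connection table handle).
#' @export
canonicalize_structure <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, !is.na(smiles),
            nzchar(trimws(smiles)))
  can <- .canon_one(smiles)
  if (is.na(can)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(can, "mol")))
  if (!any(ChemmineR::validSDF(sdfset))) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  structure(list(smiles = can, sdf = sdfset[[1]]), class = "ddi_molecule")
}

# ---- connection table -------------------------------------------------------

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                    S = 16, Cl = 17, Br = 35, I = 53)
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1)
# MDL charge codes in the atom block
.MDL_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                 `6` = -2, `7` = -3)

# Extract atoms (symbol, charge, implicit H, ring membership) and bonds
# (a1, a2, order) from a ChemmineR SDF object.
.connection_table <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) stop("empty molecule", call. = FALSE)
  symbol <- vapply(strsplit(rownames(ab), "_", fixed = TRUE), `[`, "", 1)
  charge_code <- as.character(ab[, 5])
  charge <- unname(.MDL_CHARGE[charge_code])
  charge[is.na(charge)] <- 0
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = numeric(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.numeric(bb[, 3]))
  }
  n <- nrow(ab)
  # bond-order sum per atom (aromatic order 4 contributes 1.5)
  contrib <- ifelse(bonds$order == 4, 1.5, bonds$order)
  bsum <- numeric(n)
  deg <- integer(n)
  for (i in seq_len(nrow(bonds))) {
    bsum[bonds$a1[i]] <- bsum[bonds$a1[i]] + contrib[i]
    bsum[bonds$a2[i]] <- bsum[bonds$a2[i]] + contrib[i]
    deg[bonds$a1[i]] <- deg[bonds$a1[i]] + 1L
    deg[bonds$a2[i]] <- deg[bonds$a2[i]] + 1L
  }
  val <- unname(.DEFAULT_VALENCE[symbol])
  val[is.na(val)] <- 0
  hcount <- pmax(0, round(val + charge - bsum))
  list(symbol = symbol,
       atomic_number = {
         z <- unname(.ATOMIC_NUMBER[symbol]); z[is.na(z)] <- 0; as.integer(z)
       },
       charge = as.integer(charge), hcount = as.integer(hcount),
       degree = deg, bond_sum = bsum, bonds = bonds,
       in_ring = .ring_atoms(n, bonds))
}

# An atom is in a ring iff it is incident to at least one non-bridge edge.
# Bridges are found by edge removal + reachability (molecule graphs are tiny).
.ring_atoms <- function(n, bonds) {
  in_ring <- rep(FALSE, n)
  ne <- nrow(bonds)
  if (ne == 0) return(in_ring)
  nbr <- vector("list", n)
  for (i in seq_len(ne)) {
    nbr[[bonds$a1[i]]] <- c(nbr[[bonds$a1[i]]], i)
    nbr[[bonds$a2[i]]] <- c(nbr[[bonds$a2[i]]], i)
  }
  reachable <- function(from, to, skip_edge) {
    seen <- rep(FALSE, n)
    queue <- from
    seen[from] <- TRUE
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (e in nbr[[a]]) {
        if (e == skip_edge) next
        b <- if (bonds$a1[e] == a) bonds$a2[e] else bonds$a1[e]
        if (!seen[b]) {
          if (b == to) return(TRUE)
          seen[b] <- TRUE
          queue <- c(queue, b)
        }
      }
    }
    FALSE
  }
  for (i in seq_len(ne)) {
    if (reachable(bonds$a1[i], bonds$a2[i], i)) {
      in_ring[bonds$a1[i]] <- TRUE
      in_ring[bonds$a2[i]] <- TRUE
    }
  }
  in_ring
}

# ---- Morgan fingerprint -----------------------------------------------------

#' Morgan circular fingerprint
#'
#' Hashed circular fingerprint in the ECFP family. Atom environments of
#' increasing radius are encoded by iteratively combining each atom's invariant
#' with the sorted (bond order, invariant) list of its neighbours, and every
#' environment identifier at every radius (including 0) is hashed into a
#' fixed-width bit space. The bit set is invariant under atom reordering of
#' the input structure.
#'
#' @param mol A `ddi_molecule` (from [canonicalize_structure()]) or a
#'   `ChemmineR` SDF object.
#' @param radius Maximum environment radius in bonds. Default 2.
#' @param n_bits Bit-space width. Default 2048.
#' @return A list of class `ddi_fingerprint` with sorted 0-based `bits`,
#'   `n_bits` and `radius`.
#' @export
#' @examples
#' mol <- canonicalize_structure("CCO")
#' fp <- morgan_fingerprint(mol)
#' length(fp$bits)
morgan_fingerprint <- function(mol, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0, n_bits > 0)
  sdf <- if (inherits(mol, "ddi_molecule")) mol$sdf else mol
  ct <- .connection_table(sdf)
  n <- length(ct$symbol)
  # neighbour lists as (bond order hash value, atom index)
  nbr <- vector("list", n)
  for (i in seq_len(nrow(ct$bonds))) {
    a <- ct$bonds$a1[i]; b <- ct$bonds$a2[i]
    o <- as.integer(round(ct$bonds$order[i] * 2))  # aromatic-safe integer
    nbr[[a]] <- rbind(nbr[[a]], c(o, b))
    nbr[[b]] <- rbind(nbr[[b]], c(o, a))
  }
  inv <- vapply(seq_len(n), function(a) {
    .hash32(c(ct$atomic_number[a], ct$degree[a], ct$hcount[a],
              ct$charge[a] + 8L, as.integer(ct$in_ring[a]),
              as.integer(round(ct$bond_sum[a] * 2))))
  }, numeric(1))
  ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_inv <- vapply(seq_len(n), function(a) {
        nb <- nbr[[a]]
        if (is.null(nb)) return(.hash32(c(r, inv[a])))
        env <- cbind(nb[, 1], inv[nb[, 2]])
        env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
        .hash32(c(r, inv[a], as.vector(t(env))))
      }, numeric(1))
      inv <- new_inv
      ids <- c(ids, inv)
    }
  }
  structure(list(bits = sort(unique(as.integer(ids %% n_bits))),
                 n_bits = as.integer(n_bits), radius = as.integer(radius)),
            class = "ddi_fingerprint")
}

#' Fingerprint a set of structures
#'
#' @param smiles Named character vector of SMILES (names are compound IDs).
#' @param radius,n_bits Passed to [morgan_fingerprint()].
#' @return Named list of `ddi_fingerprint` objects; unparseable structures are
#'   dropped with a warning.
#' @export
fingerprint_set <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(!is.null(names(smiles)), !anyDuplicated(names(smiles)))
  can <- canonical_smiles(smiles)
  ok <- !is.na(can)
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " unparseable structure(s): ",
            paste(names(smiles)[!ok], collapse = ", "))
  }
  if (!any(ok)) return(stats::setNames(list(), character(0)))
  sdfset <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(can[ok], names(smiles)[ok])))
  valid <- ChemmineR::validSDF(sdfset)
  sdfset <- sdfset[valid]
  out <- lapply(seq_len(length(sdfset)), function(i) {
    morgan_fingerprint(sdfset[[i]], radius = radius, n_bits = n_bits)
  })
  names(out) <- ChemmineR::sdfid(sdfset)
  out
}

# ---- Dice similarity and profiles ------------------------------------------

#' Dice similarity of two fingerprints
#'
#' `2 |A intersect B| / (|A| + |B|)` on the fingerprint bit sets.
#'
#' @param a,b `ddi_fingerprint` objects with identical `n_bits`.
#' @return A number in `[0, 1]`.
#' @export
dice_similarity <- function(a, b) {
  stopifnot(inherits(a, "ddi_fingerprint"), inherits(b, "ddi_fingerprint"))
  if (a$n_bits != b$n_bits) stop("fingerprints have different n_bits", call. = FALSE)
  if (length(a$bits) == 0 || length(b$bits) == 0) {
    stop("Dice similarity undefined for empty fingerprints", call. = FALSE)
  }
  2 * length(intersect(a$bits, b$bits)) / (length(a$bits) + length(b$bits))
}

# sparse 0/1 matrix from a fingerprint list
.fp_matrix <- function(fps) {
  n_bits <- fps[[1]]$n_bits
  Matrix::sparseMatrix(
    i = rep(seq_along(fps), lengths(lapply(fps, `[[`, "bits"))),
    j = unlist(lapply(fps, function(f) f$bits + 1L)),
    x = 1, dims = c(length(fps), n_bits))
}

#' Dice similarity matrix between two fingerprint sets
#'
#' @param query,panel Named lists of `ddi_fingerprint` objects.
#' @return Matrix of Dice coefficients, rows = query, columns = panel.
#' @export
dice_matrix <- function(query, panel) {
  stopifnot(length(query) > 0, length(panel) > 0)
  nb <- unique(c(vapply(query, `[[`, 0L, "n_bits"),
                 vapply(panel, `[[`, 0L, "n_bits")))
  if (length(nb) != 1) stop("fingerprints have different n_bits", call. = FALSE)
  qm <- .fp_matrix(query)
  pm <- .fp_matrix(panel)
  inter <- as.matrix(Matrix::tcrossprod(qm, pm))
  sizes <- outer(Matrix::rowSums(qm), Matrix::rowSums(pm), `+`)
  out <- 2 * inter / sizes
  dimnames(out) <- list(names(query), names(panel))
  out
}

#' Structural similarity profile of one compound
#'
#' Vector of Dice similarities of a query fingerprint against a fixed,
#' ordered reference panel.
#'
#' @param fp Query `ddi_fingerprint`.
#' @param panel Named list of panel `ddi_fingerprint`s (order is meaningful).
#' @param panel_id Identifier of the panel, stored as an attribute.
#' @return Named numeric vector in `[0, 1]`, length = panel size.
#' @export
similarity_profile <- function(fp, panel, panel_id = "panel") {
  stopifnot(length(panel) > 0)
  v <- vapply(panel, function(p) dice_similarity(fp, p), numeric(1))
  attr(v, "panel_id") <- panel_id
  v
}

#' Similarity profiles for a set of compounds
#'
#' @param fps Named list of query fingerprints.
#' @inheritParams similarity_profile
#' @return Matrix (query x panel) of Dice similarities with a `panel_id`
#'   attribute.
#' @export
similarity_profiles <- function(fps, panel, panel_id = "panel") {
  m <- dice_matrix(fps, panel)
  attr(m, "panel_id") <- panel_id
  m
}

# ---- PCA projection ---------------------------------------------------------

#' Fit the profile projection (PCA)
#'
#' Reduces similarity profiles to `k` principal components. Component signs
#' are fixed by making each component's largest-magnitude loading positive, so
#' refits are reproducible.
#'
#' @param profiles Matrix of similarity profiles (rows = compounds).
#' @param k Reduced dimension. Default 50.
#' @param panel_id,n_bits,radius Provenance stored with the model.
#' @return A list of class `ddi_projection` with `mean`, `components`
#'   (`k x panel`, orthonormal rows), `explained_var`, `k`, `panel_id`,
#'   `n_bits`, `radius`.
#' @export
fit_projection <- function(profiles, k = 50L, panel_id = "panel",
                           n_bits = 2048L, radius = 2L) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  k <- as.integer(k)
  if (k > nrow(profiles) || k > ncol(profiles)) {
    stop("k = ", k, " exceeds the number of profiles or the panel size",
         call. = FALSE)
  }
  pc <- stats::prcomp(profiles, center = TRUE, scale. = FALSE)
  if (k > ncol(pc$rotation)) {
    stop("k = ", k, " exceeds the feasible rank of the profile set",
         call. = FALSE)
  }
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(mean = pc$center, components = comp,
                 explained_var = pc$sdev[seq_len(k)]^2, k = k,
                 panel_id = panel_id, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "ddi_projection")
}

#' Project similarity profiles into the reduced space
#'
#' @param model A `ddi_projection`.
#' @param profiles Matrix (or single vector) of profiles of panel length.
#' @return Matrix (`n x k`) of reduced profiles.
#' @export
project_profiles <- function(model, profiles) {
  stopifnot(inherits(model, "ddi_projection"))
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  stopifnot(ncol(profiles) == length(model$mean))
  centered <- sweep(profiles, 2, model$mean)
  centered %*% t(model$components)
}

#' Pair feature vector for an ordered compound pair
#'
#' Concatenates the two PCA-reduced similarity profiles in subject-object
#' order, giving the classifier input of length `2 k`.
#'
#' @param drug_a,drug_b Compound IDs (subject first).
#' @param model A `ddi_projection`.
#' @param profiles Similarity-profile matrix with compound IDs as row names.
#' @return Numeric vector of length `2 * model$k` with an `order` attribute.
#' @export
pair_feature <- function(drug_a, drug_b, model, profiles) {
  missing <- setdiff(c(drug_a, drug_b), rownames(profiles))
  if (length(missing)) {
    stop("no similarity profile for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  red <- project_profiles(model, profiles[c(drug_a, drug_b), , drop = FALSE])
  v <- c(red[1, ], red[2, ])
  attr(v, "order") <- c(drug_a, drug_b)
  v
}

# ---- projection persistence (text format) ----------------------------------

#' Write a projection model to a text file
#'
#' Stores the model as a comment line holding a JSON header (`k`, `panel_id`,
#' `n_bits`, `radius`, `explained_var`) followed by CSV rows for the mean and
#' each component, at full double precision.
#'
#' @param model A `ddi_projection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(model, path) {
  stopifnot(inherits(model, "ddi_projection"))
  header <- jsonlite::toJSON(
    list(k = model$k, panel_id = model$panel_id, n_bits = model$n_bits,
         radius = model$radius, explained_var = model$explained_var),
    auto_unbox = TRUE, digits = NA)
  mat <- rbind(mean = model$mean, model$components)
  rownames(mat) <- c("mean", paste0("pc", seq_len(model$k)))
  lines <- c(paste0("#", header),
             paste0("panel_member,", paste(colnames(mat) %||% paste0("m", seq_len(ncol(mat))), collapse = ",")),
             vapply(seq_len(nrow(mat)), function(i) {
               paste0(rownames(mat)[i], ",",
                      paste(sprintf("%.17g", mat[i, ]), collapse = ","))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a projection model written by [write_projection()]
#'
#' @param path File path.
#' @return A `ddi_projection`.
#' @export
read_projection <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  cols <- strsplit(lines[2], ",", fixed = TRUE)[[1]][-1]
  body <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(length(cols))))
  rownames(vals) <- vapply(body, `[`, "", 1)
  colnames(vals) <- cols
  structure(list(mean = vals["mean", ],
                 components = vals[-1, , drop = FALSE],
                 explained_var = as.numeric(header$explained_var),
                 k = as.integer(header$k), panel_id = header$panel_id,
                 n_bits = as.integer(header$n_bits),
                 radius = as.integer(header$radius)),
            class = "ddi_projection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
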