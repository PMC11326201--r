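# Spatial-proximity pathogenicity scoring: a query residue is scored by its
# mean-kernel closeness to pathogenic-labeled vs benign-labeled residue
# sets, with label-permutation significance and a Ripley-style close-pair
# clustering diagnostic.

#' Read residue coordinates from a PDB-format file
#'
#' Extracts one Cα position per residue. Residue keys are
#' `"<chain>:<resno>"` strings used throughout the spatial module.
#'
#' @param path PDB-format coordinate file.
#' @return data frame of class `residue_coords`: `chain`, `resno`, `x`,
#'   `y`, `z`, `key`.
#' @export
read_residue_coords <- function(path) {
  pdb <- bio3d::read.pdb(path)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  at <- pdb$atom[ca$atom, ]
  df <- data.frame(chain = at$chain, resno = at$resno,
                   x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  df$key <- paste(df$chain, df$resno, sep = ":")
  if (anyDuplicated(df$key))
    vu_stop("vustruct_input_error", "duplicate residue key(s) in %s", path)
  class(df) <- c("residue_coords", "data.frame")
  df
}

#' Pairwise Euclidean residue distances
#'
#' @param coords a `residue_coords` data frame (or any data frame with
#'   `x`, `y`, `z`, `key`).
#' @return symmetric distance matrix in Angstrom, dimnames = residue keys.
#' @export
pairwise_distances <- function(coords) {
  if (anyDuplicated(coords$key))
    vu_stop("vustruct_input_error", "duplicate residue keys")
  if (!all(is.finite(as.matrix(coords[, c("x", "y", "z")]))))
    vu_stop("vustruct_input_error", "non-finite coordinates")
  D <- as.matrix(dist(coords[, c("x", "y", "z")]))
  dimnames(D) <- list(coords$key, coords$key)
  D
}

#' Proximity kernels
#'
#' Distance kernels for [proximity()]: reciprocal `1/(1+d)` (default),
#' Gaussian `exp(-d^2 / (2 sigma^2))` with `sigma = 8` Angstrom, and
#' hard-shell `[d <= cutoff]` with `cutoff = 10` Angstrom. All are
#' non-increasing in distance and equal 1 at `d = 0`.
#'
#' @param name one of `"reciprocal"`, `"gaussian"`, `"hardshell"`, or a
#'   kernel function which is returned unchanged.
#' @param sigma Gaussian width (Angstrom).
#' @param cutoff hard-shell radius (Angstrom).
#' @return a vectorised function of distance.
#' @export
pathprox_kernel <- function(name = "reciprocal", sigma = 8, cutoff = 10) {
  if (is.function(name)) return(name)
  switch(match.arg(name, c("reciprocal", "gaussian", "hardshell")),
         reciprocal = function(d) 1 / (1 + d),
         gaussian = function(d) exp(-d^2 / (2 * sigma^2)),
         hardshell = function(d) as.numeric(d <= cutoff))
}

# distance from the query to each key in `keys`; the query may map to
# several chains of a homomultimer, in which case the minimum over mapped
# copies is used.
query_distances <- function(q, keys, D) {
  missing <- setdiff(c(q, keys), rownames(D))
  if (length(missing) > 0)
    vu_stop("vustruct_input_error", "residue key(s) not in structure: %s",
            paste(missing, collapse = ", "))
  sub <- D[q, keys, drop = FALSE]
  apply(sub, 2, min)
}

#' Mean-kernel proximity of a query residue to a residue set
#'
#' `(1/|S|) * sum over s in S of K(d(q, s))`; strictly decreasing in each
#' member's distance for strictly decreasing kernels.
#'
#' @param q query residue key (`"chain:resno"`); a vector of keys when the
#'   query position maps to several chains (minimum distance is used).
#' @param S character vector of residue keys (non-empty, excluding `q`).
#' @param coords `residue_coords`, or a precomputed [pairwise_distances()]
#'   matrix.
#' @param kernel kernel function or name (see [pathprox_kernel()]).
#' @return numeric proximity.
#' @export
proximity <- function(q, S, coords, kernel = "reciprocal") {
  if (length(S) == 0)
    vu_stop("vustruct_input_error", "proximity is undefined for an empty set")
  if (any(S %in% q))
    vu_stop("vustruct_input_error", "query residue must not be in the set")
  D <- if (is.matrix(coords)) coords else pairwise_distances(coords)
  K <- pathprox_kernel(kernel)
  mean(K(query_distances(q, S, D)))
}

#' Spatial pathogenicity score
#'
#' `proximity(q, P) - proximity(q, B)`: positive when the query residue
#' sits closer (in kernel terms) to the pathogenic-labeled cluster than to
#' the benign-labeled one.
#'
#' @param q query residue key(s).
#' @param P,B non-empty, disjoint character vectors of residue keys
#'   (pathogenic- and benign-labeled), neither containing `q`.
#' @inheritParams proximity
#' @return numeric score.
#' @export
pathprox_score <- function(q, P, B, coords, kernel = "reciprocal") {
  if (length(intersect(P, B)) > 0)
    vu_stop("vustruct_input_error", "pathogenic and benign sets overlap")
  D <- if (is.matrix(coords)) coords else pairwise_distances(coords)
  proximity(q, P, D, kernel) - proximity(q, B, D, kernel)
}

#' Label-permutation significance of the spatial score
#'
#' Null model: the pathogenic label set is re-drawn uniformly at random
#' (size `|P|`) from the observed sites `P` and `B`, the remainder labeled
#' benign, and the score recomputed. The p-value is
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`; ties are counted with a
#' small numeric tolerance so that rigid-motion jitter cannot flip them.
#'
#' @inheritParams pathprox_score
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @return object of class `pathprox_result`: `score`, `p_value`,
#'   `n_perm`, `seed`, `n_pathogenic`, `n_benign`.
#' @export
permutation_pvalue <- function(q, P, B, coords, n_perm = 999, seed = 1,
                               kernel = "reciprocal") {
  if (n_perm < 1) vu_stop("vustruct_input_error", "n_perm must be >= 1")
  pool <- c(P, B)
  if (length(pool) < 2)
    vu_stop("vustruct_input_error", "need at least 2 labeled sites")
  D <- if (is.matrix(coords)) coords else pairwise_distances(coords)
  obs <- pathprox_score(q, P, B, D, kernel)
  K <- pathprox_kernel(kernel)
  k <- K(query_distances(q, pool, D))      # kernel value per candidate site
  np <- length(P); n <- length(pool)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, np)
      mean(k[idx]) - mean(k[-idx])
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs - 1e-9)) / (n_perm + 1)
  structure(list(score = obs, p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), n_pathogenic = np,
                 n_benign = length(B)),
            class = "pathprox_result")
}

#' @export
print.pathprox_result <- function(x, ...) {
  cat(sprintf("<pathprox> score %.4f, p = %.4g (%d pathogenic vs %d benign, %d permutations, seed %d)\n",
              x$score, x$p_value, x$n_pathogenic, x$n_benign, x$n_perm, x$seed))
  invisible(x)
}

#' Ripley-style close-pair clustering diagnostic
#'
#' Counts unordered pairs within each radius among a residue set and
#' compares against a permutation envelope built from uniformly drawn
#' subsets of the same size from all residues in the structure. Counts
#' above the upper envelope flag clustering at that radius.
#'
#' @param S character vector of residue keys (`|S| >= 2`).
#' @param coords `residue_coords` or a distance matrix.
#' @param radii positive ascending radii (Angstrom).
#' @param n_perm envelope permutations.
#' @param seed integer seed.
#' @param level envelope coverage (default 0.95: 2.5th/97.5th percentiles).
#' @return object of class `ripley_result`: `radii`, `pair_counts`,
#'   `envelope_lo`, `envelope_hi`, `clustered` (logical per radius).
#' @export
clustering_diagnostic <- function(S, coords, radii = c(4, 6, 8, 10, 12, 16, 20, 24),
                                  n_perm = 999, seed = 1, level = 0.95) {
  if (length(S) < 2) vu_stop("vustruct_input_error", "need |S| >= 2")
  if (any(diff(radii) <= 0) || any(radii <= 0))
    vu_stop("vustruct_input_error", "radii must be positive and ascending")
  D <- if (is.matrix(coords)) coords else pairwise_distances(coords)
  if (length(S) > nrow(D))
    vu_stop("vustruct_input_error", "set larger than the structure")
  if (!all(S %in% rownames(D)))
    vu_stop("vustruct_input_error", "residue key(s) not in structure")
  count_pairs <- function(keys) {
    d <- D[keys, keys][upper.tri(diag(length(keys)))]
    vapply(radii, function(t) sum(d <= t), numeric(1))
  }
  obs <- count_pairs(S)
  all_keys <- rownames(D)
  perm <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm),
             function(i) count_pairs(sample(all_keys, length(S))),
             numeric(length(radii))))
  })
  alpha <- (1 - level) / 2
  lo <- apply(perm, 2, quantile, probs = alpha)
  hi <- apply(perm, 2, quantile, probs = 1 - alpha)
  structure(list(radii = radii, pair_counts = obs,
                 envelope_lo = unname(lo), envelope_hi = unname(hi),
                 clustered = obs > hi, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "ripley_result")
}

#' @export
print.ripley_result <- function(x, ...) {
  cat("<clustering diagnostic>\n")
  print(data.frame(radius = x$radii, pairs = x$pair_counts,
                   lo = x$envelope_lo, hi = x$envelope_hi,
                   clustered = x$clustered))
  invisible(x)
}

#' Read a labeled-variant table (TSV)
#'
#' Columns: `transcript_position` (1-based), `label`
#' (`pathogenic`/`benign`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, colClasses = c("integer", "character"))
  stopifnot(all(c("transcript_position", "label") %in% names(df)))
  df
}
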