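#' @noRd
check_dist_matrix <- function(X, name = deparse(substitute(X))) {
  stopifnot(is.matrix(X), nrow(X) == ncol(X))
  if (max(abs(X - t(X))) > 1e-8) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(X)) > 1e-8)) {
    stop(name, " must have a zero diagonal", call. = FALSE)
  }
  invisible(X)
}

#' @noRd
resid_on <- function(a, z) {
  fit <- stats::lm.fit(cbind(1, z), a)
  fit$residuals
}

mantel_result <- function(r, p, permutations, method, masked, seed,
                          n_pairs) {
  structure(list(statistic = r, p.value = p, permutations = permutations,
                 method = method, masked = masked, seed = seed,
                 n_pairs = n_pairs),
            class = "asn_mantel")
}

#' @export
print.asn_mantel <- function(x, ...) {
  cat(x$method, if (x$masked) "(threshold-masked pairs)" else "(full matrix)",
      "\n")
  cat(sprintf("  r = %.6f, p = %.6f (%d permutations, one-tailed, %d pairs)\n",
              x$statistic, x$p.value, x$permutations, x$n_pairs))
  invisible(x)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation between the strictly-lower-triangle vectors of two
#' conformal distance matrices, with significance from simultaneous
#' row/column permutation of one matrix. The test is one-tailed against a
#' positive association (the isolation-by-distance expectation):
#' `p = (#\{r_perm >= r_obs\} + 1) / (permutations + 1)`, so the smallest
#' attainable p at 1000 permutations is `1/1001`.
#'
#' With a `mask`, the correlation is computed only over the masked pairs
#' (e.g. pairs connected in a thresholded network); permutations relabel the
#' nodes of `X` and re-read values at the fixed mask positions.
#'
#' @param X,Y symmetric distance matrices with zero diagonals and identical
#'   ID ordering.
#' @param permutations number of label permutations.
#' @param seed RNG seed (fixed seed gives bit-identical p-values).
#' @param mask optional: a logical symmetric matrix, or an ASN whose edges
#'   define the retained pairs.
#' @return An `asn_mantel` object with elements `statistic` (r), `p.value`,
#'   `permutations`, `masked`, `seed`, `n_pairs`.
#' @export
#' @examples
#' set.seed(7)
#' pts <- matrix(runif(20), 10)
#' X <- as.matrix(dist(pts))
#' mantel_test(X, X + as.matrix(dist(matrix(runif(20), 10))) / 5,
#'   permutations = 99, seed = 1
#' )
mantel_test <- function(X, Y, permutations = 1000, seed = NULL,
                        mask = NULL) {
  check_dist_matrix(X, "X")
  check_dist_matrix(Y, "Y")
  stopifnot(identical(dim(X), dim(Y)))
  n <- nrow(X)
  pos <- mask_positions(mask, n)
  x <- X[pos]
  y <- Y[pos]
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant distance vector", call. = FALSE)
  }
  r <- cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(i) {
    p <- sample.int(n)
    cor(X[p, p][pos], y)
  }, numeric(1))
  pval <- (sum(r_perm >= r) + 1) / (permutations + 1)
  mantel_result(r, pval, permutations, "Mantel test",
                masked = !is_full_mask(mask), seed = seed,
                n_pairs = length(x))
}

#' Partial Mantel test
#'
#' Correlation between `X` and `Y` after each is regressed on `Z` over the
#' lower-triangle (or masked) pair vectors. Permutations relabel the nodes
#' of `X` and re-residualize the permuted matrix against `Z` at every draw;
#' one-tailed against a positive partial association.
#'
#' @inheritParams mantel_test
#' @param Z the conditioning distance matrix.
#' @return An `asn_mantel` object.
#' @export
partial_mantel_test <- function(X, Y, Z, permutations = 1000, seed = NULL,
                                mask = NULL) {
  check_dist_matrix(X, "X")
  check_dist_matrix(Y, "Y")
  check_dist_matrix(Z, "Z")
  stopifnot(identical(dim(X), dim(Y)), identical(dim(X), dim(Z)))
  n <- nrow(X)
  pos <- mask_positions(mask, n)
  z <- Z[pos]
  ry <- resid_on(Y[pos], z)
  if (length(z) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(ry) <= 1e-8 * max(stats::sd(Y[pos]), 1e-300)) {
    stop("partial correlation undefined: Y is collinear with Z",
         call. = FALSE)
  }
  r <- cor(resid_on(X[pos], z), ry)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(permutations), function(i) {
    p <- sample.int(n)
    cor(resid_on(X[p, p][pos], z), ry)
  }, numeric(1))
  pval <- (sum(r_perm >= r) + 1) / (permutations + 1)
  mantel_result(r, pval, permutations, "Partial Mantel test",
                masked = !is_full_mask(mask), seed = seed,
                n_pairs = length(z))
}

#' Mantel test restricted to network-connected pairs
#'
#' Convenience wrapper: [mantel_test()] (or [partial_mantel_test()] when
#' `Z` is given) over only the pairs joined by an edge in the thresholded
#' network — the "threshold matrices" variant.
#'
#' @inheritParams partial_mantel_test
#' @param mask a logical symmetric pair mask or an ASN.
#' @param Z optional conditioning matrix.
#' @return An `asn_mantel` object.
#' @export
masked_mantel_test <- function(X, Y, mask, permutations = 1000,
                               seed = NULL, Z = NULL) {
  if (is.null(Z)) {
    mantel_test(X, Y, permutations = permutations, seed = seed, mask = mask)
  } else {
    partial_mantel_test(X, Y, Z, permutations = permutations, seed = seed,
                        mask = mask)
  }
}

#' @noRd
mask_positions <- function(mask, n) {
  lower <- lower.tri(matrix(0, n, n))
  if (is.null(mask)) return(which(lower))
  if (inherits(mask, "igraph")) {
    mask <- as.matrix(igraph::as_adjacency_matrix(mask, sparse = TRUE)) > 0
  }
  stopifnot(is.matrix(mask), identical(dim(mask), c(n, n)))
  pos <- which(lower & mask)
  if (length(pos) < 3L) {
    stop("mask retains fewer than 3 pairs", call. = FALSE)
  }
  pos
}

#' @noRd
is_full_mask <- function(mask) is.null(mask)

#' Isolation-by-distance test battery
#'
#' Runs the eight standard tests for one dataset: cultural distance against
#' geographic and chronological distance, simple and partial (conditioning
#' on the other distance), each on the full matrices and on the
#' threshold-masked pairs.
#'
#' @param S an `asn_similarity` (cultural distance is `1 - S`).
#' @param distances an `asn_distances` from [distance_matrices()].
#' @param network the thresholded ASN supplying the pair mask.
#' @param permutations,seed passed to the tests.
#' @return data.frame with columns `test`, `scope`, `r`, `p`, `n_pairs`.
#' @export
mantel_table <- function(S, distances, network, permutations = 1000,
                         seed = NULL) {
  Dc <- cultural_distance(S)
  Dg <- distances$geo_km
  Dt <- distances$chrono_years
  runs <- list(
    list("cultural vs geographic", function(m)
      mantel_test(Dc, Dg, permutations, seed, mask = m)),
    list("cultural vs geographic ~ chronological", function(m)
      partial_mantel_test(Dc, Dg, Dt, permutations, seed, mask = m)),
    list("cultural vs chronological", function(m)
      mantel_test(Dc, Dt, permutations, seed, mask = m)),
    list("cultural vs chronological ~ geographic", function(m)
      partial_mantel_test(Dc, Dt, Dg, permutations, seed, mask = m))
  )
  rows <- list()
  for (run in runs) {
    for (scope in c("full", "threshold")) {
      m <- if (scope == "full") NULL else network
      res <- run[[2L]](m)
      rows[[length(rows) + 1L]] <- data.frame(
        test = run[[1L]], scope = scope, r = res$statistic,
        p = res$p.value, n_pairs = res$n_pairs, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
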