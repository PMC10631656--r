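#' Brainerd-Robinson similarity on the unit scale
#'
#' Similarity between two count assemblages: 1 minus half the city-block
#' distance between the assemblages' within-assemblage trait proportions.
#' This is the classical 0-200 Brainerd-Robinson statistic divided by 200,
#' so it lives on \[0, 1\] with 1 meaning identical trait proportions. It is
#' invariant to multiplying either assemblage's counts by a positive
#' constant.
#'
#' @param a,b non-negative count vectors over the same ordered trait list;
#'   each must have a positive total.
#' @return similarity in \[0, 1\].
#' @seealso [jaccard_index()] for presence/absence data.
#' @export
#' @examples
#' brainerd_robinson(c(3, 1), c(1, 3)) # 0.5
brainerd_robinson <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  sa <- sum(a)
  sb <- sum(b)
  if (!isTRUE(sa > 0) || !isTRUE(sb > 0)) {
    stop("proportions undefined: assemblage with zero total count",
         call. = FALSE)
  }
  1 - sum(abs(a / sa - b / sb)) / 2
}

#' Jaccard similarity between presence/absence vectors
#'
#' Size of the intersection over the size of the union of the trait sets
#' present in either assemblage. Undefined (an error) when both assemblages
#' are empty.
#'
#' @param a,b binary (0/1 or logical) vectors over the same ordered trait
#'   list.
#' @return similarity in \[0, 1\].
#' @export
#' @examples
#' jaccard_index(c(1, 1, 0), c(0, 1, 1)) # 1/3
jaccard_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a)
  b <- as.logical(b)
  if (anyNA(a) || anyNA(b)) stop("presence vectors must be 0/1", call. = FALSE)
  u <- sum(a | b)
  if (u == 0L) {
    stop("Jaccard undefined: both assemblages are empty", call. = FALSE)
  }
  sum(a & b) / u
}

#' Pairwise similarity matrix for an assemblage
#'
#' Computes the full symmetric occupation-by-occupation similarity matrix.
#' The index follows the data mode: Brainerd-Robinson for counts, Jaccard
#' for presence/absence, both on \[0, 1\] with a unit diagonal.
#'
#' @param x an [asn_assemblage()].
#' @return An `asn_similarity` object: list with `ids`, the symmetric matrix
#'   `S`, and `index` (`"BR"` or `"Jaccard"`).
#' @export
similarity_matrix <- function(x) {
  stopifnot(inherits(x, "asn_assemblage"))
  v <- x$values
  ids <- rownames(v)
  if (x$mode == "counts") {
    rs <- rowSums(v)
    if (any(rs <= 0)) {
      stop("zero row sum for occupation(s): ",
           paste(ids[rs <= 0], collapse = ", "), call. = FALSE)
    }
    p <- v / rs
    S <- 1 - as.matrix(stats::dist(p, method = "manhattan")) / 2
    index <- "BR"
  } else {
    m <- (v > 0) * 1
    inter <- tcrossprod(m)
    pres <- rowSums(m)
    if (any(pres == 0)) {
      stop("empty presence set for occupation(s): ",
           paste(ids[pres == 0], collapse = ", "), call. = FALSE)
    }
    uni <- outer(pres, pres, "+") - inter
    S <- inter / uni
    index <- "Jaccard"
  }
  diag(S) <- 1
  S <- (S + t(S)) / 2 # enforce exact symmetry against rounding
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, S = S, index = index), class = "asn_similarity")
}

#' @export
print.asn_similarity <- function(x, ...) {
  off <- x$S[lower.tri(x$S)]
  cat(x$index, " similarity matrix, ", length(x$ids), " occupations\n",
      sep = "")
  cat(sprintf("  off-diagonal range: %.4f - %.4f (mean %.4f)\n",
              min(off), max(off), mean(off)))
  invisible(x)
}

#' Cultural distance derived from a similarity matrix
#'
#' The complement `1 - S`: a symmetric matrix with zero diagonal, used as
#' the cultural distance in Mantel isolation-by-distance tests. Being a
#' monotone linear transform, Mantel correlations computed on it match
#' correlations on the similarities up to sign.
#'
#' @param S an `asn_similarity` object or a symmetric similarity matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
cultural_distance <- function(S) {
  if (inherits(S, "asn_similarity")) S <- S$S
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  D <- 1 - S
  diag(D) <- 0
  D
}

#' Write a square labelled matrix as CSV
#'
#' Square CSV with the occupation IDs as both header row and first column
#' (the layout of published similarity/distance matrix worksheets).
#'
#' @param m matrix with dimnames, or an `asn_similarity`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  if (inherits(m, "asn_similarity")) m <- m$S
  write.csv(as.data.frame(m, check.names = FALSE), path, row.names = TRUE)
  invisible(path)
}
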