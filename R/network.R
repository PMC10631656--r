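#' Connectivity-preserving similarity threshold
#'
#' The similarity graph is pruned at the minimum edge weight that keeps the
#' network a single connected component — optionally allowing a few extreme
#' outlier nodes to fall off. Formally: the largest observed off-diagonal
#' weight `t` such that the graph with edges `{w >= t}` has a connected
#' component of at least `n - max_outliers` nodes. With `max_outliers = 0`
#' this equals the bottleneck (minimum edge weight) of a maximum spanning
#' tree of the complete similarity graph.
#'
#' @param S an `asn_similarity` object or symmetric similarity matrix.
#' @param max_outliers number of nodes allowed to stay disconnected.
#' @return the threshold, with attributes `outliers` (IDs outside the main
#'   component at that threshold) and `component_size`.
#' @export
#' @examples
#' S <- matrix(c(1, .9, .5, .9, 1, .2, .5, .2, 1), 3,
#'   dimnames = rep(list(c("a", "b", "c")), 2)
#' )
#' connectivity_threshold(S) # 0.5
connectivity_threshold <- function(S, max_outliers = 0) {
  if (inherits(S, "asn_similarity")) S <- S$S
  n <- nrow(S)
  stopifnot(n >= 2, max_outliers >= 0)
  w <- sort(unique(S[lower.tri(S)]), decreasing = TRUE)
  target <- n - max_outliers
  for (t in w) {
    g <- graph_at_threshold(S, t)
    comp <- igraph::components(g)
    if (max(comp$csize) >= target) {
      main <- which.max(comp$csize)
      out <- rownames(S)[comp$membership != main]
      return(structure(t, outliers = out,
                       component_size = max(comp$csize)))
    }
  }
  stop("no threshold keeps ", target,
       " nodes in one component, even at the minimum weight", call. = FALSE)
}

#' @noRd
graph_at_threshold <- function(S, threshold) {
  A <- S
  diag(A) <- 0
  A[A < threshold] <- 0
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Build an archaeological similarity network
#'
#' Nodes are all occupations in the similarity matrix (isolated nodes are
#' kept); an undirected edge joins every pair whose similarity is at or
#' above the threshold, carrying the similarity as its weight. Edge weights
#' are never rescaled: thickness in a plot is the similarity itself.
#'
#' @param S an `asn_similarity` object or symmetric similarity matrix.
#' @param threshold edge-weight cut in \[0, 1\]; typically the value from
#'   [connectivity_threshold()], or an imposed published value.
#' @param meta optional occupation metadata (data.frame as in
#'   [asn_assemblage()]) attached as vertex attributes `culture`, `lat`,
#'   `lon`, `date_early`, `date_late`, `sequence`.
#' @return an igraph object with graph attributes `threshold` and (when `S`
#'   is an `asn_similarity`) `index`.
#' @export
build_asn <- function(S, threshold, meta = NULL) {
  index <- NULL
  if (inherits(S, "asn_similarity")) {
    index <- S$index
    S <- S$S
  }
  stopifnot(is.matrix(S), threshold >= 0, threshold <= 1)
  g <- graph_at_threshold(S, threshold)
  g <- igraph::set_graph_attr(g, "threshold", as.numeric(threshold))
  if (!is.null(index)) g <- igraph::set_graph_attr(g, "index", index)
  if (!is.null(meta)) {
    if (inherits(meta, "asn_assemblage")) meta <- meta$meta
    ord <- match(igraph::V(g)$name, meta$occupation)
    if (anyNA(ord)) stop("metadata does not cover all nodes", call. = FALSE)
    igraph::V(g)$culture <- as.character(meta$culture)[ord]
    igraph::V(g)$lat <- meta$lat[ord]
    igraph::V(g)$lon <- meta$lon[ord]
    igraph::V(g)$date_early <- meta$date_early[ord]
    igraph::V(g)$date_late <- meta$date_late[ord]
    igraph::V(g)$sequence <- vapply(meta$sequences[ord], paste, "",
                                    collapse = ";")
  }
  g
}

#' Node layout for plotting an ASN
#'
#' Either the Fruchterman-Reingold force-directed layout (deterministic
#' given `seed`) or a manual geographic layout that places each node at its
#' (longitude, latitude).
#'
#' @param network an ASN from [build_asn()].
#' @param method `"fruchterman_reingold"` or `"geographic"`.
#' @param seed RNG seed for the force-directed layout.
#' @return numeric matrix of (x, y) positions, rownames the occupation IDs.
#' @export
asn_layout <- function(network, method = c("fruchterman_reingold",
                                           "geographic"), seed = 1L) {
  method <- match.arg(method)
  if (method == "geographic") {
    lon <- igraph::V(network)$lon
    lat <- igraph::V(network)$lat
    if (is.null(lon) || is.null(lat) || anyNA(lon) || anyNA(lat)) {
      bad <- igraph::V(network)$name[is.null(lon) | is.na(lon) | is.na(lat)]
      stop("geographic layout needs coordinates; missing for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    xy <- cbind(x = lon, y = lat)
  } else {
    set.seed(seed)
    xy <- igraph::layout_with_fr(network,
                                 weights = igraph::E(network)$weight)
    colnames(xy) <- c("x", "y")
  }
  rownames(xy) <- igraph::V(network)$name
  xy
}
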