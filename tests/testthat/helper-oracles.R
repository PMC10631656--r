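# Independent brute-force oracles, deliberately free of igraph and of the
# package's own code paths.

# component sizes by breadth-first search over a logical adjacency matrix
bf_component_sizes <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      size <- size + 1L
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# scan sorted candidate cuts, highest first
bf_threshold <- function(S, max_outliers = 0) {
  n <- nrow(S)
  for (t in sort(unique(S[lower.tri(S)]), decreasing = TRUE)) {
    adj <- S >= t
    diag(adj) <- FALSE
    if (max(bf_component_sizes(adj)) >= n - max_outliers) return(t)
  }
  stop("infeasible")
}

# bottleneck (minimum edge weight) of a maximum spanning tree, by Prim
mst_bottleneck <- function(S) {
  n <- nrow(S)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  bottleneck <- Inf
  for (step in seq_len(n - 1L)) {
    best <- -Inf
    bj <- NA_integer_
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        if (S[i, j] > best) {
          best <- S[i, j]
          bj <- j
        }
      }
    }
    in_tree[bj] <- TRUE
    bottleneck <- min(bottleneck, best)
  }
  bottleneck
}

bf_density <- function(adj) {
  n <- nrow(adj)
  sum(adj[lower.tri(adj)]) / (n * (n - 1) / 2)
}

bf_transitivity <- function(adj) {
  n <- nrow(adj)
  tri <- 0L
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 1L, n - 1L)) {
      for (k in seq(j + 1L, n)) {
        if (adj[i, j] && adj[j, k] && adj[i, k]) tri <- tri + 1L
      }
    }
  }
  deg <- rowSums(adj)
  triples <- sum(deg * (deg - 1) / 2)
  3 * tri / triples
}

# betweenness by explicit enumeration of every shortest path
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  bfs_dist <- function(s) {
    d <- rep(Inf, n)
    d[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in which(adj[v, ])) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d
  }
  for (s in seq_len(n - 1L)) {
    d <- bfs_dist(s)
    for (t in seq(s + 1L, n)) {
      if (is.infinite(d[t])) next
      # walk back from t along the BFS level structure, listing every path
      paths <- list(t)
      repeat {
        done <- all(vapply(paths, function(p) p[1L] == s, logical(1)))
        if (done) break
        paths <- unlist(lapply(paths, function(p) {
          if (p[1L] == s) return(list(p))
          pred <- which(adj[p[1L], ] & d == d[p[1L]] - 1)
          lapply(pred, function(q) c(q, p))
        }), recursive = FALSE)
      }
      k <- length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        btw[interior] <- btw[interior] + 1 / k
      }
    }
  }
  btw
}

# valid random similarity matrix: symmetric, unit diagonal, [0, 1]
random_similarity <- function(n, ids = sprintf("o%02d", seq_len(n))) {
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  S[lower.tri(S)] <- runif(n * (n - 1) / 2)
  S <- S + t(S)
  diag(S) <- 1
  S
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  adj[lower.tri(adj)] <- runif(n * (n - 1) / 2) < p
  adj | t(adj)
}

graph_from_adj <- function(adj) {
  dimnames(adj) <- list(sprintf("v%d", seq_len(nrow(adj))),
                        sprintf("v%d", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# tiny assemblage fixtures built in code
toy_meta <- function(n, culture = rep("IMP", n), lat = NULL, lon = NULL,
                     early = NULL, late = NULL) {
  meta <- data.frame(
    occupation = sprintf("T%02d", seq_len(n)),
    site = sprintf("site %d", seq_len(n)),
    culture = culture,
    lat = if (is.null(lat)) seq(40, 44, length.out = n) else lat,
    lon = if (is.null(lon)) seq(0, 8, length.out = n) else lon,
    date_early = if (is.null(early)) rep(7800, n) else early,
    date_late = if (is.null(late)) rep(7500, n) else late,
    stringsAsFactors = FALSE
  )
  meta$sequences <- rep(list(1L), n)
  meta
}

toy_counts <- function(values, ...) {
  n <- nrow(values)
  rownames(values) <- sprintf("T%02d", seq_len(n))
  colnames(values) <- sprintf("tr%d", seq_len(ncol(values)))
  asn_assemblage(toy_meta(n, ...), values, mode = "counts")
}

# random uniform points -> Euclidean distance matrix (a valid metric)
random_distance_matrix <- function(n, dim = 2) {
  as.matrix(stats::dist(matrix(runif(n * dim), n)))
}
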