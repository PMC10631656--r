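#' Network density over the full node set
#'
#' `2E / (n(n-1))`, counting isolated nodes in `n`.
#'
#' @param network an ASN from [build_asn()] (any igraph object works).
#' @return density in \[0, 1\].
#' @export
asn_density <- function(network) {
  n <- igraph::vcount(network)
  stopifnot(n >= 2)
  2 * igraph::ecount(network) / (n * (n - 1))
}

#' Cluster coefficient of the thresholded network
#'
#' Computed on the binarized threshold graph. `"transitivity"` (the
#' default) is the global ratio 3 x triangles / connected triples;
#' `"avg_local"` is the mean of per-node local clustering with isolated and
#' degree-1 nodes contributing 0.
#'
#' @param network an ASN.
#' @param variant `"transitivity"` or `"avg_local"`.
#' @return coefficient in \[0, 1\].
#' @export
cluster_coefficient <- function(network,
                                variant = c("transitivity", "avg_local")) {
  variant <- match.arg(variant)
  stopifnot(igraph::vcount(network) >= 3)
  if (variant == "transitivity") {
    igraph::transitivity(network, type = "global")
  } else {
    igraph::transitivity(network, type = "localaverage", isolates = "zero")
  }
}

#' Weighted node centralities
#'
#' Strength (weighted degree: sum of incident similarity weights),
#' eigenvector centrality of the weighted adjacency matrix (scores scaled to
#' mean 1), and shortest-path betweenness on the binarized threshold graph
#' with equal-length paths split fractionally.
#'
#' @param network an ASN.
#' @return data.frame with columns `occupation`, `strength`, `eigenvector`,
#'   `betweenness`.
#' @export
node_centralities <- function(network) {
  if (igraph::ecount(network) == 0L) {
    stop("eigenvector centrality undefined on an edgeless graph",
         call. = FALSE)
  }
  w <- igraph::E(network)$weight
  strength <- igraph::strength(network, weights = w)
  # leading eigenvector of the weighted adjacency via a full symmetric
  # eigendecomposition: deterministic across runs, exact for these sizes
  A <- as.matrix(igraph::as_adjacency_matrix(network, attr = "weight",
                                             sparse = TRUE))
  ev <- eigen(A, symmetric = TRUE)$vectors[, 1L]
  ev <- ev * sign(sum(ev))
  eig <- pmax(ev, 0) # Perron vector of a non-negative matrix
  eig <- eig / mean(eig)
  btw <- igraph::betweenness(network, weights = NA)
  data.frame(occupation = igraph::V(network)$name,
             strength = as.numeric(strength),
             eigenvector = as.numeric(eig),
             betweenness = as.numeric(btw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Freeman centralization of a centrality score
#'
#' `sum(max(c) - c)` divided by the theoretical maximum of that sum for a
#' graph of the same size: `(n-1)(n-2)` for degree (attained by the star
#' graph when weights are at most 1), `(n-1)^2 (n-2) / 2` for betweenness,
#' and `n-1` for eigenvector scores rescaled to a maximum of 1.
#'
#' @param scores numeric vector of node centralities.
#' @param kind `"degree"`, `"eigenvector"`, or `"betweenness"`.
#' @param n number of nodes (defaults to `length(scores)`).
#' @return normalized centralization in \[0, 1\].
#' @export
centralization <- function(scores, kind = c("degree", "eigenvector",
                                            "betweenness"),
                           n = length(scores)) {
  kind <- match.arg(kind)
  stopifnot(n >= 2)
  denom <- switch(kind,
    degree = (n - 1) * (n - 2),
    betweenness = (n - 1)^2 * (n - 2) / 2,
    eigenvector = n - 1
  )
  if (denom <= 0) {
    stop("centralization undefined: zero theoretical maximum for n = ", n,
         call. = FALSE)
  }
  if (kind == "eigenvector") scores <- scores / max(scores)
  sum(max(scores) - scores) / denom
}

#' Interval statistics of the plotted edges
#'
#' Minimum, mean and maximum of the edge weights, great-circle distances and
#' chronological distances over the edges retained by the threshold, with
#' the occupation pairs attaining the extremes.
#'
#' @param network an ASN.
#' @param distances an `asn_distances` object from [distance_matrices()],
#'   or `NULL` to report edge weights only.
#' @return data.frame with one row per metric: `min`, `mean`, `max`,
#'   `min_pair`, `max_pair`.
#' @export
interval_stats <- function(network, distances = NULL) {
  el <- igraph::as_edgelist(network)
  if (nrow(el) == 0L) stop("no edges retained", call. = FALSE)
  pairs <- paste(el[, 1L], el[, 2L], sep = "-")
  one <- function(vals, metric) {
    data.frame(metric = metric, min = min(vals), mean = mean(vals),
               max = max(vals),
               min_pair = pairs[which.min(vals)],
               max_pair = pairs[which.max(vals)],
               stringsAsFactors = FALSE)
  }
  out <- one(igraph::E(network)$weight, "edge_weight")
  if (!is.null(distances)) {
    km <- distances$geo_km[el]
    yr <- distances$chrono_years[el]
    out <- rbind(out, one(km, "geo_km"), one(yr, "chrono_years"))
  }
  row.names(out) <- NULL
  out
}

#' Main cultural units of the Early Neolithic Western Mediterranean
#'
#' Groups the seven regional archaeological cultures into the three main
#' units: Impressa (IMP), Cardial (TyC, RPC, LCC, VC) and Epicardial (LCE,
#' VE). Occupations coded `NONE` belong to no unit.
#'
#' @return named list of culture-code vectors.
#' @export
main_cultural_units <- function() {
  list(Impressa = "IMP",
       Cardial = c("TyC", "RPC", "LCC", "VC"),
       Epicardial = c("LCE", "VE"))
}

#' Statistics of the subgraph induced by a cultural unit
#'
#' Density and cluster coefficient of the threshold network restricted to
#' the unit's occupations (induced subgraph: only edges between unit
#' members count).
#'
#' @param network an ASN with a `culture` vertex attribute.
#' @param unit character vector of culture codes defining the unit.
#' @param cluster_variant passed to [cluster_coefficient()].
#' @return list with `n_nodes`, `density`, `cluster_coefficient` (NA when
#'   the unit has fewer than 3 members).
#' @export
unit_stats <- function(network, unit, cluster_variant = "transitivity") {
  cult <- igraph::V(network)$culture
  if (is.null(cult)) stop("network has no culture attribute", call. = FALSE)
  members <- which(cult %in% unit)
  if (length(members) < 2L) {
    stop("unit has fewer than 2 member occupations; density undefined",
         call. = FALSE)
  }
  sub <- igraph::induced_subgraph(network, members)
  list(n_nodes = length(members),
       density = asn_density(sub),
       cluster_coefficient = if (length(members) >= 3L) {
         cluster_coefficient(sub, cluster_variant)
       } else NA_real_)
}

#' Intra-cultural similarity radius
#'
#' For each within-unit occupation pair, the geographic distance divided by
#' the pair's similarity — a radius over which a unit maintains a given
#' level of resemblance. Pairs at identical coordinates contribute 0
#' regardless of similarity; zero-similarity pairs at positive distance
#' contribute `Inf`. An empty pair set yields `min = Inf`, `max = -Inf`,
#' `mean = NaN` (the empty-range convention).
#'
#' @param S an `asn_similarity` or similarity matrix.
#' @param geo_km geographic distance matrix with matching dimnames.
#' @param members occupation IDs of the unit.
#' @param scope `"full"` (all within-unit pairs) or `"threshold"` (only
#'   pairs connected in `network`).
#' @param network required for `scope = "threshold"`.
#' @return list with `min`, `mean`, `max`, `n_pairs`.
#' @export
similarity_radius <- function(S, geo_km, members,
                              scope = c("full", "threshold"),
                              network = NULL) {
  scope <- match.arg(scope)
  if (inherits(S, "asn_similarity")) S <- S$S
  members <- intersect(members, rownames(S))
  pairs <- if (length(members) >= 2L) {
    t(utils::combn(members, 2L))
  } else {
    matrix(character(0), 0L, 2L)
  }
  if (scope == "threshold") {
    if (is.null(network)) {
      stop("scope = 'threshold' needs the network", call. = FALSE)
    }
    if (nrow(pairs) > 0L) {
      connected <- apply(pairs, 1L, function(p) {
        igraph::are_adjacent(network, p[1L], p[2L])
      })
      pairs <- pairs[connected, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L) {
    return(list(min = Inf, mean = NaN, max = -Inf, n_pairs = 0L))
  }
  km <- geo_km[pairs]
  s <- S[pairs]
  r <- ifelse(km == 0, 0, km / s) # s = 0 with km > 0 gives Inf, in-band
  list(min = min(r), mean = mean(r), max = max(r), n_pairs = nrow(pairs))
}

#' Full descriptive-statistics report for an ASN
#'
#' Assembles the network-level, node-level, interval and per-cultural-unit
#' tables in one object.
#'
#' @param network an ASN from [build_asn()].
#' @param S the `asn_similarity` the network was built from (needed for
#'   similarity radii); optional.
#' @param distances an `asn_distances`; optional.
#' @param units named list of culture-code vectors, `NULL` for one unit per
#'   distinct culture code (the code `NONE` is always excluded from unit
#'   statistics).
#' @param cluster_variant passed to [cluster_coefficient()].
#' @return An `asn_stats` object: list of data.frames `network_level`,
#'   `node_level`, `intervals`, `unit_level`.
#' @export
network_stats <- function(network, S = NULL, distances = NULL, units = NULL,
                          cluster_variant = "transitivity") {
  n <- igraph::vcount(network)
  cent <- node_centralities(network)
  network_level <- data.frame(
    n_nodes = n,
    n_edges = igraph::ecount(network),
    threshold = igraph::graph_attr(network, "threshold"),
    density = asn_density(network),
    cluster_coefficient = cluster_coefficient(network, cluster_variant),
    centralization_degree = centralization(cent$strength, "degree"),
    centralization_eigen = centralization(cent$eigenvector, "eigenvector"),
    centralization_betweenness = centralization(cent$betweenness,
                                                "betweenness")
  )
  intervals <- interval_stats(network, distances)
  cult <- igraph::V(network)$culture
  unit_level <- NULL
  if (!is.null(cult)) {
    if (is.null(units)) {
      codes <- setdiff(sort(unique(cult)), "NONE")
      units <- as.list(codes)
      names(units) <- codes
    }
    rows <- lapply(names(units), function(u) {
      st <- tryCatch(unit_stats(network, units[[u]], cluster_variant),
                     error = function(e) list(n_nodes = sum(cult %in%
                                                              units[[u]]),
                                              density = NA_real_,
                                              cluster_coefficient = NA_real_))
      row <- data.frame(unit = u, n_nodes = st$n_nodes,
                        density = st$density,
                        cluster_coefficient = st$cluster_coefficient,
                        stringsAsFactors = FALSE)
      if (!is.null(S) && !is.null(distances)) {
        members <- igraph::V(network)$name[cult %in% units[[u]]]
        for (sc in c("full", "threshold")) {
          sr <- similarity_radius(S, distances$geo_km, members, scope = sc,
                                  network = network)
          row[[paste0("radius_", sc, "_min")]] <- sr$min
          row[[paste0("radius_", sc, "_mean")]] <- sr$mean
          row[[paste0("radius_", sc, "_max")]] <- sr$max
        }
      }
      row
    })
    unit_level <- do.call(rbind, rows)
  }
  structure(list(network_level = network_level, node_level = cent,
                 intervals = intervals, unit_level = unit_level),
            class = "asn_stats")
}

#' @export
print.asn_stats <- function(x, ...) {
  cat("ASN descriptive statistics\n")
  nl <- x$network_level
  cat(sprintf("  %d nodes, %d edges (threshold %.4f)\n", nl$n_nodes,
              nl$n_edges, nl$threshold))
  cat(sprintf("  density %.4f, cluster coefficient %.4f\n", nl$density,
              nl$cluster_coefficient))
  cat(sprintf(
    "  centralization: degree %.5f, eigen %.5f, betweenness %.3g\n",
    nl$centralization_degree, nl$centralization_eigen,
    nl$centralization_betweenness))
  top <- x$node_level[order(-x$node_level$strength)[1:min(3,
    nrow(x$node_level))], ]
  cat("  top strength:",
      paste(sprintf("%s:%.4f", top$occupation, top$strength),
            collapse = ", "), "\n")
  invisible(x)
}
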