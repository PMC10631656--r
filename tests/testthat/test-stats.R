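test_that("density covers complete, empty and brute-force random cases", {
  K4 <- graph_from_adj(matrix(TRUE, 4, 4) & !diag(4))
  expect_equal(asn_density(K4), 1)
  empty <- build_asn(random_similarity(5), 1) # cut above any weight
  expect_equal(asn_density(empty), 0)
  set.seed(61)
  for (i in 1:25) {
    adj <- random_adjacency(sample(4:10, 1))
    expect_equal(asn_density(graph_from_adj(adj)), bf_density(adj))
  }
})

test_that("cluster coefficient matches closed forms and brute force", {
  K5 <- graph_from_adj(matrix(TRUE, 5, 5) & !diag(5))
  expect_equal(cluster_coefficient(K5, "transitivity"), 1)
  expect_equal(cluster_coefficient(K5, "avg_local"), 1)
  star <- matrix(FALSE, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- TRUE
  gs <- graph_from_adj(star)
  expect_equal(cluster_coefficient(gs, "transitivity"), 0)
  expect_equal(cluster_coefficient(gs, "avg_local"), 0)
  set.seed(62)
  for (i in 1:20) {
    adj <- random_adjacency(sample(5:10, 1), p = 0.5)
    g <- graph_from_adj(adj)
    tr <- bf_transitivity(adj)
    if (!is.nan(tr)) {
      expect_equal(cluster_coefficient(g, "transitivity"), tr)
    }
  }
})

test_that("betweenness (binarized, fractional split) matches enumeration", {
  path3 <- matrix(FALSE, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- TRUE
  g <- graph_from_adj(path3)
  igraph::E(g)$weight <- c(0.9, 0.3) # weights must not affect betweenness
  cent <- node_centralities(g)
  expect_equal(cent$betweenness, c(0, 1, 0))
  set.seed(63)
  for (i in 1:15) {
    adj <- random_adjacency(sample(4:9, 1), p = 0.45)
    if (!any(adj)) next
    g <- graph_from_adj(adj)
    expect_equal(node_centralities(g)$betweenness, bf_betweenness(adj))
  }
})

test_that("strength and eigenvector follow the stated conventions", {
  S <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  S["a", "b"] <- S["b", "a"] <- 0.5
  S["b", "c"] <- S["c", "b"] <- 0.7
  diag(S) <- 1
  g <- build_asn(S, 0.4)
  cent <- node_centralities(g)
  expect_equal(cent$strength[cent$occupation == "b"], 1.2)
  expect_equal(mean(cent$eigenvector), 1) # mean-1 scaling
  # eigenvector direction invariant to rescaling all weights
  g2 <- g
  igraph::E(g2)$weight <- igraph::E(g2)$weight * 13
  expect_equal(node_centralities(g2)$eigenvector, cent$eigenvector)
  edgeless <- build_asn(S, 1)
  expect_error(node_centralities(edgeless), "edgeless")
})

test_that("Freeman centralization is 1 for a star and 0 for regular graphs", {
  n <- 7
  star_scores <- c(n - 1, rep(1, n - 1)) # unit-weight star strengths
  expect_equal(centralization(star_scores, "degree"), 1)
  expect_equal(centralization(rep(3, n), "degree"), 0)
  expect_equal(centralization(rep(0.4, n), "betweenness"), 0)
  star_btw <- c((n - 1) * (n - 2) / 2, rep(0, n - 1))
  expect_equal(centralization(star_btw, "betweenness"), 1)
  expect_error(centralization(c(1, 2), "degree"), "undefined")
  # bounded after normalization for centralities of actual ASNs
  set.seed(64)
  for (i in 1:15) {
    S <- random_similarity(sample(4:12, 1))
    g <- build_asn(S, as.numeric(connectivity_threshold(S)))
    cent <- node_centralities(g)
    for (kind in c("degree", "eigenvector", "betweenness")) {
      sc <- switch(kind, degree = cent$strength,
                   eigenvector = cent$eigenvector,
                   betweenness = cent$betweenness)
      v <- centralization(sc, kind)
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("interval statistics report extremes with their pairs", {
  v <- matrix(c(5, 1, 4, 2, 1, 5), 3, byrow = TRUE)
  x <- toy_counts(v, lat = c(40, 40, 42), lon = c(0, 1, 3),
                  early = c(7900, 7700, 7800), late = c(7600, 7500, 7400))
  S <- similarity_matrix(x)
  D <- distance_matrices(x)
  g <- build_asn(S, 0)
  iv <- interval_stats(g, D)
  expect_equal(iv$metric, c("edge_weight", "geo_km", "chrono_years"))
  expect_true(all(iv$min <= iv$mean & iv$mean <= iv$max))
  lt <- lower.tri(D$geo_km)
  expect_equal(iv$max[iv$metric == "geo_km"], max(D$geo_km[lt]))
  expect_equal(iv$min[iv$metric == "edge_weight"], min(S$S[lt]))
  # single edge: min = mean = max
  g1 <- build_asn(S, max(S$S[lt]))
  iv1 <- interval_stats(g1, D)
  expect_equal(iv1$min, iv1$mean)
  expect_equal(iv1$mean, iv1$max)
})

test_that("unit statistics use the induced subgraph", {
  set.seed(65)
  v <- matrix(rpois(6 * 5, 4) + 1, 6, 5)
  x <- toy_counts(v, culture = c("RPC", "RPC", "RPC", "LCE", "LCE", "NONE"))
  S <- similarity_matrix(x)
  g <- build_asn(S, 0, meta = x) # complete graph: any unit is a clique
  expect_equal(unit_stats(g, "RPC")$density, 1)
  expect_equal(unit_stats(g, "RPC")$cluster_coefficient, 1)
  expect_error(unit_stats(g, "NONE"), "fewer than 2")
  expect_error(unit_stats(g, "VC"), "fewer than 2")
  both <- unit_stats(g, c("RPC", "LCE"))
  expect_equal(both$n_nodes, 5)
})

test_that("similarity radius handles zeros, infinities and empty units", {
  ids <- c("u1", "u2", "u3")
  S <- matrix(c(1, .5, 0, .5, 1, .25, 0, .25, 1), 3,
              dimnames = list(ids, ids))
  km <- matrix(c(0, 100, 50, 100, 0, 80, 50, 80, 0), 3,
               dimnames = list(ids, ids))
  r <- similarity_radius(S, km, c("u1", "u2"))
  expect_equal(r$min, 200)
  expect_equal(r$mean, 200)
  expect_equal(r$max, 200)
  # zero similarity at positive distance -> Inf, in-band
  expect_equal(similarity_radius(S, km, c("u1", "u3"))$max, Inf)
  # identical coordinates dominate any similarity
  km0 <- km
  km0["u1", "u2"] <- km0["u2", "u1"] <- 0
  expect_equal(similarity_radius(S, km0, c("u1", "u2"))$max, 0)
  # empty pair set: the empty-range convention of the published tables
  single <- similarity_radius(S, km, "u1")
  expect_equal(single$min, Inf)
  expect_equal(single$max, -Inf)
  expect_true(is.nan(single$mean))
  # threshold scope is bounded by full scope when no zero-similarity pairs
  set.seed(66)
  S2 <- random_similarity(8)
  km2 <- random_distance_matrix(8) * 500
  dimnames(km2) <- dimnames(S2)
  g2 <- build_asn(S2, as.numeric(connectivity_threshold(S2)))
  full <- similarity_radius(S2, km2, rownames(S2), "full")
  thr <- similarity_radius(S2, km2, rownames(S2), "threshold", network = g2)
  expect_gte(thr$min, full$min)
  expect_lte(thr$max, full$max)
})

test_that("network_stats assembles a coherent report", {
  a <- simulate_assemblage(sim_config(seed = 8), "counts")
  S <- similarity_matrix(a)
  g <- build_asn(S, as.numeric(connectivity_threshold(S)), meta = a)
  st <- network_stats(g, S = S, distances = distance_matrices(a))
  expect_s3_class(st, "asn_stats")
  expect_equal(nrow(st$node_level), igraph::vcount(g))
  expect_true(st$network_level$density >= 0 &&
                st$network_level$density <= 1)
  expect_equal(sort(st$unit_level$unit), c("CU1", "CU2", "CU3"))
  expect_true(all(c("radius_full_mean", "radius_threshold_mean") %in%
                    names(st$unit_level)))
})
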