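test_that("Mantel r equals the lower-triangle Pearson correlation", {
  set.seed(81)
  X <- random_distance_matrix(12)
  expect_equal(mantel_test(X, X, permutations = 19, seed = 1)$statistic, 1)
  Y <- random_distance_matrix(12)
  m <- mantel_test(X, Y, permutations = 99, seed = 1)
  lt <- lower.tri(X)
  expect_equal(m$statistic, cor(X[lt], Y[lt]))
  # independent route: vegan computes the same statistic
  expect_equal(m$statistic,
               unname(vegan::mantel(as.dist(X), as.dist(Y),
                                    permutations = 9)$statistic))
  expect_gte(m$p.value, 1 / 100)
  expect_error(mantel_test(X, matrix(0, 12, 12)), "constant")
})

test_that("permutation p-values have the 1/(B+1) floor and fixed-seed identity", {
  set.seed(82)
  pts <- matrix(runif(40), 20)
  X <- as.matrix(dist(pts))
  Y <- as.matrix(dist(pts + rnorm(40, 0, 0.01))) # near-copy: strong signal
  m <- mantel_test(X, Y, permutations = 1000, seed = 7)
  expect_equal(m$p.value, 1 / 1001) # the printed floor at 1000 permutations
  m2 <- mantel_test(X, Y, permutations = 1000, seed = 7)
  expect_identical(m$p.value, m2$p.value)
  expect_identical(m$statistic, m2$statistic)
})

test_that("Mantel r is invariant to positive affine transforms", {
  set.seed(83)
  X <- random_distance_matrix(10)
  Y <- random_distance_matrix(10)
  r0 <- mantel_test(X, Y, permutations = 9, seed = 1)$statistic
  r1 <- mantel_test(X * 3.7, Y, permutations = 9, seed = 1)$statistic
  expect_equal(r0, r1)
})

test_that("partial Mantel controls the conditioning matrix", {
  set.seed(84)
  X <- random_distance_matrix(15)
  Y <- random_distance_matrix(15)
  # controlling Y for itself leaves nothing to correlate with
  expect_error(partial_mantel_test(X, Y, Y, permutations = 99, seed = 2),
               "collinear")
  # vegan's partial correlation agrees with the residual-correlation route
  Z <- random_distance_matrix(15)
  ours <- partial_mantel_test(X, Y, Z, permutations = 49, seed = 3)$statistic
  ref <- unname(vegan::mantel.partial(as.dist(X), as.dist(Y), as.dist(Z),
                                      permutations = 9)$statistic)
  expect_equal(ours, ref)
})

test_that("an uncorrelated conditioning matrix barely shifts r", {
  set.seed(85)
  deltas <- replicate(30, {
    n <- 30
    X <- random_distance_matrix(n)
    Y0 <- random_distance_matrix(n)
    lt <- lower.tri(X)
    Y <- X * 0.6 # correlated pair ...
    Y[lt] <- Y[lt] + Y0[lt] * 0.4
    Y <- (Y + t(Y)) / 2
    diag(Y) <- 0
    Z <- random_distance_matrix(n) # ... conditioned on independent noise
    abs(partial_mantel_test(X, Y, Z, permutations = 9)$statistic -
          mantel_test(X, Y, permutations = 9)$statistic)
  })
  expect_lt(mean(deltas), 0.02)
})

test_that("masked Mantel reduces to the full test and handles tiny masks", {
  set.seed(86)
  X <- random_distance_matrix(10)
  Y <- random_distance_matrix(10)
  full_mask <- matrix(TRUE, 10, 10)
  m1 <- mantel_test(X, Y, permutations = 99, seed = 5)
  m2 <- masked_mantel_test(X, Y, full_mask, permutations = 99, seed = 5)
  expect_equal(m1$statistic, m2$statistic)
  expect_equal(m1$p.value, m2$p.value)
  # three masked pairs: a correlation on 3 points
  mask <- matrix(FALSE, 10, 10)
  mask[2, 1] <- mask[5, 3] <- mask[9, 6] <- TRUE
  mask <- mask | t(mask)
  m3 <- masked_mantel_test(X, Y, mask, permutations = 49, seed = 5)
  expect_equal(m3$n_pairs, 3L)
  mask2 <- matrix(FALSE, 10, 10)
  mask2[2, 1] <- TRUE
  expect_error(masked_mantel_test(X, Y, mask2 | t(mask2)), "fewer than 3")
})

test_that("a network mask restricts the test to connected pairs", {
  a <- simulate_assemblage(sim_config(seed = 87), "counts")
  S <- similarity_matrix(a)
  D <- distance_matrices(a)
  g <- build_asn(S, as.numeric(connectivity_threshold(S)), meta = a)
  mm <- masked_mantel_test(cultural_distance(S), D$geo_km, g,
                           permutations = 99, seed = 1)
  expect_equal(mm$n_pairs, igraph::ecount(g))
  expect_true(mm$masked)
  tab <- mantel_table(S, D, g, permutations = 49, seed = 1)
  expect_equal(nrow(tab), 8L)
  expect_setequal(unique(tab$scope), c("full", "threshold"))
  expect_true(all(tab$p >= 1 / 50 & tab$p <= 1))
})
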