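test_that("assemblage CSV round-trip is value-identical", {
  a <- simulate_assemblage(sim_config(seed = 201), "counts")
  f <- withr::local_tempfile(fileext = ".csv")
  write_assemblage(a, f)
  b <- read_assemblage(f, mode = "counts")
  expect_identical(b$values, a$values)
  expect_equal(b$meta$occupation, a$meta$occupation)
  expect_equal(b$meta$lat, a$meta$lat)
  expect_equal(b$meta$sequences, a$meta$sequences)
  expect_true(all(attr(b, "load_report")$loaded))
})

test_that("a tiny hand-written CSV loads with row sums preserved", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "occupation,site,culture,lat,lon,date_early,date_late,sequences,ta,tb",
    "A1,Cave,IMP,43.1,7.2,7900,7700,1,5,2",
    "A2,Cave,IMP,43.1,7.2,7800,7600,1,1,6",
    "A3,Shelter,RPC,41.0,2.0,7400,7200,2,3,3"
  ), f)
  a <- read_assemblage(f, mode = "counts")
  expect_equal(nrow(a$values), 3)
  expect_equal(unname(rowSums(a$values)), c(7, 7, 6))
  expect_equal(colnames(a$values), c("ta", "tb"))
})

test_that("schema errors and validation errors name the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("occupation,site,culture,lat,lon,date_early,sequences,ta",
               "A1,Cave,IMP,43.1,7.2,7900,1,5"), f)
  expect_error(read_assemblage(f, mode = "counts"), "date_late")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "occupation,site,culture,lat,lon,date_early,date_late,sequences,ta,tb",
    "A1,Cave,IMP,43.1,7.2,7900,7700,1,-2,1"
  ), f2)
  expect_error(read_assemblage(f2, mode = "counts"), "A1/ta")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "occupation,site,culture,lat,lon,date_early,date_late,sequences,ta,tb",
    "A1,Cave,IMP,43.1,7.2,7900,7700,1,2,1",
    "A1,Cave,IMP,43.1,7.2,7800,7600,1,1,1"
  ), f3)
  expect_error(read_assemblage(f3, mode = "counts"), "unique")
})

test_that("rows with missing coordinates are flagged, never dropped", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "occupation,site,culture,lat,lon,date_early,date_late,sequences,ta,tb",
    "A1,Cave,IMP,43.1,7.2,7900,7700,1,5,2",
    "A2,Cave,IMP,,,7800,7600,1,1,6"
  ), f)
  a <- read_assemblage(f, mode = "counts")
  expect_equal(nrow(a$values), 2)
  expect_equal(a$flagged, "A2")
  rep <- attr(a, "load_report")
  expect_equal(rep$flagged, c(FALSE, TRUE))
})

test_that("networks round-trip exactly through GraphML and edge lists", {
  S <- matrix(c(1, .9, .5, .9, 1, .44, .5, .44, 1), 3,
              dimnames = rep(list(c("n1", "n2", "n3")), 2))
  g <- build_asn(S, 0.44)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, f1, "graphml")
  g1 <- read_network(f1, "graphml")
  expect_equal(sort(igraph::V(g1)$name), sort(igraph::V(g)$name))
  el <- igraph::as_edgelist(g)
  el1 <- igraph::as_edgelist(g1)
  expect_equal(el[order(el[, 1], el[, 2]), ], el1[order(el1[, 1],
                                                        el1[, 2]), ])
  expect_identical(sort(igraph::E(g1)$weight), sort(igraph::E(g)$weight))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_network(g, f2, "edgelist_csv")
  tab <- read.csv(f2)
  expect_equal(nrow(tab), 3)
  expect_identical(sort(tab$weight), sort(igraph::E(g)$weight))
  g2 <- read_network(f2, "edgelist_csv")
  expect_identical(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight))
  # degenerate: threshold above every weight leaves a header-only edge list
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_network(build_asn(S, 0.95), f3, "edgelist_csv")
  expect_equal(nrow(read.csv(f3)), 0)
  expect_equal(names(read.csv(f3)),
               c("source", "target", "weight", "km", "years"))
})

test_that("GraphML preserves node metadata and isolated nodes", {
  a <- simulate_assemblage(sim_config(seed = 202), "counts")
  S <- similarity_matrix(a)
  g <- build_asn(S, 0.9, meta = a) # sparse: leaves isolates
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, f, "graphml")
  g2 <- read_network(f, "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  ord <- match(igraph::V(g)$name, igraph::V(g2)$name)
  expect_equal(igraph::V(g2)$culture[ord], igraph::V(g)$culture)
  expect_equal(igraph::V(g2)$lat[ord], igraph::V(g)$lat)
})

test_that("statistics tables round-trip at full precision", {
  a <- simulate_assemblage(sim_config(seed = 203), "counts")
  S <- similarity_matrix(a)
  g <- build_asn(S, as.numeric(connectivity_threshold(S)), meta = a)
  st <- network_stats(g, S = S, distances = distance_matrices(a))
  d <- withr::local_tempdir()
  paths <- write_stats(st, d)
  expect_true(all(file.exists(paths)))
  node <- read_stats(paths[["node_level"]])
  expect_equal(nrow(node), igraph::vcount(g))
  expect_equal(node$strength, st$node_level$strength)
  expect_equal(node$betweenness, st$node_level$betweenness)
  net <- read_stats(paths[["network_level"]])
  expect_equal(net$density, st$network_level$density)
  expect_equal(net$centralization_eigen,
               st$network_level$centralization_eigen)
})
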