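#' Run configuration for the full ASN workflow
#'
#' Collects every tunable of the pipeline in one serializable list. Can be
#' built in R or loaded from a YAML file with [read_run_config()]. The
#' resolved configuration (including auto-selected thresholds) is written
#' next to the outputs of [run_asn_pipeline()], so a published run can be
#' reproduced by pinning the resolved thresholds.
#'
#' @param index `"auto"` (follow the data mode), `"br"` or `"jaccard"`.
#' @param threshold `"auto"` or a numeric edge-weight cut; for `"auto"` the
#'   connectivity-preserving threshold is selected per network.
#' @param max_outliers tolerated disconnected nodes in auto-thresholding.
#' @param cluster_variant passed to [cluster_coefficient()].
#' @param chrono_method passed to [chrono_distance()].
#' @param sequence_pairs which consecutive-sequence networks to build.
#' @param permutations,seed Mantel settings.
#' @param units cultural units for unit statistics (`NULL` = one per code).
#' @return An `asn_run_config` list.
#' @export
run_config <- function(index = "auto", threshold = "auto", max_outliers = 0,
                       cluster_variant = "transitivity",
                       chrono_method = "euclidean2d",
                       sequence_pairs = c("12", "23"),
                       permutations = 1000, seed = 1L, units = NULL) {
  structure(
    list(index = index, threshold = threshold, max_outliers = max_outliers,
         cluster_variant = cluster_variant, chrono_method = chrono_method,
         sequence_pairs = sequence_pairs, permutations = permutations,
         seed = as.integer(seed), units = units),
    class = "asn_run_config"
  )
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return An `asn_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals),
                                     names(formals(run_config)))])
}

#' Run the full similarity-network workflow
#'
#' For the complete dataset and each configured pair of consecutive time
#' sequences: computes the similarity matrix, resolves the threshold,
#' builds the ASN, extracts the descriptive-statistics report, both
#' layouts, and the Mantel isolation-by-distance battery. With an
#' `output_dir`, every artefact is written to disk (similarity matrix CSV,
#' GraphML, edge-list CSV, statistics CSVs, layout CSV, Mantel CSV) along
#' with a `provenance.yaml` recording the resolved configuration, node and
#' edge counts, and seeds.
#'
#' @param assemblage an [asn_assemblage()].
#' @param config an [run_config()].
#' @param output_dir optional directory for the output bundle.
#' @return list of per-subset results (`all`, `seq12`, `seq23`), each with
#'   `similarity`, `threshold`, `network`, `stats`, `layout_fr`,
#'   `layout_geo`, `distances`, `mantel`; plus `provenance`.
#' @export
run_asn_pipeline <- function(assemblage, config = run_config(),
                             output_dir = NULL) {
  stopifnot(inherits(assemblage, "asn_assemblage"),
            inherits(config, "asn_run_config"))
  subsets <- list(all = assemblage)
  for (pair in config$sequence_pairs) {
    subsets[[paste0("seq", pair)]] <-
      tryCatch(sequence_pair_subset(assemblage, pair),
               error = function(e) NULL)
  }
  subsets <- Filter(Negate(is.null), subsets)
  results <- list()
  prov <- list(index = config$index, chrono_method = config$chrono_method,
               cluster_variant = config$cluster_variant,
               max_outliers = config$max_outliers,
               permutations = config$permutations, seed = config$seed,
               networks = list())
  for (nm in names(subsets)) {
    sub <- subsets[[nm]]
    res <- tryCatch(
      run_one_network(sub, config),
      error = function(e) stop("pipeline stage '", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    results[[nm]] <- res
    prov$networks[[nm]] <- list(
      n_nodes = igraph::vcount(res$network),
      n_edges = igraph::ecount(res$network),
      threshold = as.numeric(res$threshold),
      outliers = as.list(attr(res$threshold, "outliers"))
    )
    if (!is.null(output_dir)) {
      d <- file.path(output_dir, nm)
      if (!dir.exists(d)) dir.create(d, recursive = TRUE)
      write_square_matrix(res$similarity, file.path(d, "similarity.csv"))
      write_network(res$network, file.path(d, "network.graphml"), "graphml")
      write_network(res$network, file.path(d, "edges.csv"), "edgelist_csv",
                    distances = res$distances)
      write_stats(res$stats, d, prefix = "stats")
      write.csv(data.frame(occupation = rownames(res$layout_fr),
                           fr_x = res$layout_fr[, 1L],
                           fr_y = res$layout_fr[, 2L],
                           geo_x = res$layout_geo[, 1L],
                           geo_y = res$layout_geo[, 2L]),
                file.path(d, "layout.csv"), row.names = FALSE)
      write.csv(res$mantel, file.path(d, "mantel.csv"), row.names = FALSE)
    }
  }
  if (!is.null(output_dir)) {
    yaml::write_yaml(prov, file.path(output_dir, "provenance.yaml"))
  }
  results$provenance <- prov
  results
}

#' @noRd
run_one_network <- function(sub, config) {
  wanted <- switch(config$index, auto = NULL, br = "counts",
                   jaccard = "presence",
                   stop("unknown index: ", config$index, call. = FALSE))
  if (!is.null(wanted) && !identical(sub$mode, wanted)) {
    stop("index '", config$index, "' needs ", wanted, " data but mode is ",
         sub$mode, call. = FALSE)
  }
  S <- similarity_matrix(sub)
  thr <- if (identical(config$threshold, "auto")) {
    connectivity_threshold(S, max_outliers = config$max_outliers)
  } else {
    structure(as.numeric(config$threshold), outliers = character(0))
  }
  g <- build_asn(S, as.numeric(thr), meta = sub)
  D <- distance_matrices(sub, chrono_method = config$chrono_method)
  st <- network_stats(g, S = S, distances = D, units = config$units,
                      cluster_variant = config$cluster_variant)
  mt <- mantel_table(S, D, g, permutations = config$permutations,
                     seed = config$seed)
  list(similarity = S, threshold = thr, network = g, distances = D,
       stats = st,
       layout_fr = asn_layout(g, "fruchterman_reingold",
                              seed = config$seed),
       layout_geo = asn_layout(g, "geographic"),
       mantel = mt)
}
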