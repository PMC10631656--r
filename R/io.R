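#' Write an ASN to GraphML or an edge-list CSV
#'
#' GraphML preserves the full network (node attributes, isolated nodes,
#' weights) and round-trips exactly through [read_network()]. The edge-list
#' CSV has columns `source, target, weight, km, years` (`km`/`years` filled
#' from `distances` when given, `NA` otherwise); it records edges only, so
#' isolated nodes are not representable in that format.
#'
#' @param network an ASN from [build_asn()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @param distances optional `asn_distances` used to fill the `km` and
#'   `years` columns.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("graphml", "edgelist_csv"),
                          distances = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    out <- data.frame(
      source = el[, 1L], target = el[, 2L],
      weight = if (nrow(el)) igraph::E(network)$weight else numeric(0),
      km = if (!is.null(distances) && nrow(el)) distances$geo_km[el]
           else rep(NA_real_, nrow(el)),
      years = if (!is.null(distances) && nrow(el))
                distances$chrono_years[el]
              else rep(NA_real_, nrow(el)),
      stringsAsFactors = FALSE
    )
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edgelist_csv"`.
#' @return an igraph object; for `edgelist_csv` the vertex set is the set
#'   of edge endpoints.
#' @export
read_network <- function(path, format = c("graphml", "edgelist_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  el <- read.csv(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el[, c("source", "target"),
                                        drop = FALSE],
                                     directed = FALSE)
  if (nrow(el)) igraph::E(g)$weight <- el$weight
  g
}

#' Write a statistics report as CSV tables
#'
#' One CSV per table of an `asn_stats` report (`network_level`,
#' `node_level`, `intervals`, `unit_level`), at full double precision and
#' with a deterministic column order.
#'
#' @param report an `asn_stats` from [network_stats()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_stats <- function(report, dir, prefix = "asn") {
  stopifnot(inherits(report, "asn_stats"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("network_level", "node_level", "intervals", "unit_level")
  paths <- character(0)
  for (tb in tables) {
    x <- report[[tb]]
    if (is.null(x)) next
    p <- file.path(dir, paste0(prefix, "_", tb, ".csv"))
    write.csv(format(x, digits = 17, trim = TRUE, scientific = FALSE),
              p, row.names = FALSE, quote = TRUE)
    paths[tb] <- p
  }
  invisible(paths)
}

#' Read back a statistics CSV written by [write_stats()]
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_stats <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(x)) {
    num <- suppressWarnings(as.numeric(x[[j]]))
    if (!anyNA(num) || all(is.na(num) == is.na(x[[j]]))) x[[j]] <- num
  }
  x
}
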