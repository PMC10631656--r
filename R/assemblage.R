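#' Occupation-by-trait assemblage tables
#'
#' An `asn_assemblage` bundles an occupation-by-trait numeric table with
#' per-occupation metadata: occupation identifier, site name, archaeological
#' culture code, WGS84 coordinates, the occupation's calibrated date range
#' (cal BP, so `date_early >= date_late`), and its time-sequence membership.
#'
#' @param meta data.frame with columns `occupation`, `site`, `culture`,
#'   `lat`, `lon`, `date_early`, `date_late`, and `sequences` (a list column
#'   of integer vectors, or a character column like `"1;2"`).
#' @param values numeric matrix, one row per occupation (rownames must match
#'   `meta$occupation`), one column per trait.
#' @param mode `"counts"` (non-negative integers, positive row sums) or
#'   `"presence"` (0/1).
#' @param date_bounds permissible range for dates in cal BP; the Early
#'   Neolithic Western Mediterranean study data fall in `c(6000, 9000)`.
#'   Use `NULL` to skip the bound check.
#'
#' @return An object of class `asn_assemblage`: a list with elements `meta`,
#'   `values`, `mode`, and `flagged` (occupations loaded with missing
#'   coordinates or dates).
#' @export
#' @examples
#' meta <- data.frame(
#'   occupation = c("A1", "A2"), site = c("Cave A", "Cave A"),
#'   culture = c("IMP", "IMP"), lat = c(43.8, 43.8), lon = c(7.5, 7.5),
#'   date_early = c(7900, 7800), date_late = c(7700, 7600)
#' )
#' meta$sequences <- list(1L, 1L)
#' x <- asn_assemblage(meta, matrix(c(3, 1, 1, 3), 2,
#'   dimnames = list(c("A1", "A2"), c("t1", "t2"))
#' ), mode = "counts")
#' x
asn_assemblage <- function(meta, values, mode = c("counts", "presence"),
                           date_bounds = c(6000, 9000)) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(meta), is.matrix(values))
  values <- structure(as.numeric(values), dim = dim(values),
                      dimnames = dimnames(values))
  required <- c("occupation", "site", "culture", "lat", "lon",
                "date_early", "date_late", "sequences")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$occupation)) {
    stop("occupation IDs must be unique; duplicated: ",
         paste(unique(meta$occupation[duplicated(meta$occupation)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.character(meta$sequences)) {
    meta$sequences <- parse_sequences(meta$sequences)
  }
  if (!is.list(meta$sequences)) meta$sequences <- as.list(meta$sequences)
  if (is.null(rownames(values))) rownames(values) <- meta$occupation
  if (!identical(rownames(values), as.character(meta$occupation))) {
    stop("rownames(values) must match meta$occupation", call. = FALSE)
  }
  x <- structure(
    list(meta = meta, values = values, mode = mode,
         flagged = character(0)),
    class = "asn_assemblage"
  )
  validate_assemblage(x, date_bounds = date_bounds)
}

parse_sequences <- function(s) {
  lapply(strsplit(as.character(s), "[;, ]+"), function(v) {
    v <- suppressWarnings(as.integer(v[nzchar(v)]))
    sort(unique(v[!is.na(v)]))
  })
}

#' @noRd
validate_assemblage <- function(x, date_bounds = c(6000, 9000)) {
  meta <- x$meta
  v <- x$values
  occ <- as.character(meta$occupation)
  bad_lat <- which(!is.na(meta$lat) & (meta$lat < -90 | meta$lat > 90))
  bad_lon <- which(!is.na(meta$lon) & (meta$lon < -180 | meta$lon > 180))
  if (length(bad_lat) || length(bad_lon)) {
    stop("coordinates out of range for occupation(s): ",
         paste(occ[union(bad_lat, bad_lon)], collapse = ", "), call. = FALSE)
  }
  both <- !is.na(meta$date_early) & !is.na(meta$date_late)
  rev_dates <- which(both & meta$date_early < meta$date_late)
  if (length(rev_dates)) {
    stop("date_early must be >= date_late (cal BP counts backwards) for: ",
         paste(occ[rev_dates], collapse = ", "), call. = FALSE)
  }
  if (!is.null(date_bounds)) {
    out <- which(both & (meta$date_early > max(date_bounds) |
                           meta$date_late < min(date_bounds)))
    if (length(out)) {
      stop("dates outside bounds [", min(date_bounds), ", ",
           max(date_bounds), "] cal BP for: ",
           paste(occ[out], collapse = ", "), call. = FALSE)
    }
  }
  bad_cells <- function(test) {
    idx <- which(test, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    paste0(occ[idx[, 1L]], "/", colnames(v)[idx[, 2L]], collapse = ", ")
  }
  if (x$mode == "counts") {
    neg <- bad_cells(!is.na(v) & (v < 0 | v != round(v)))
    if (!is.null(neg)) {
      stop("counts must be non-negative integers; offending ",
           "occupation/trait: ", neg, call. = FALSE)
    }
    zero <- which(rowSums(v, na.rm = TRUE) <= 0)
    if (length(zero)) {
      stop("zero row sum (no recorded traits) for occupation(s): ",
           paste(occ[zero], collapse = ", "), call. = FALSE)
    }
  } else {
    nb <- bad_cells(!is.na(v) & !(v %in% c(0, 1)))
    if (!is.null(nb)) {
      stop("presence values must be 0/1; offending occupation/trait: ",
           nb, call. = FALSE)
    }
  }
  # flag (never drop) records unusable for spatial/chronological analyses
  flag <- !stats::complete.cases(meta[, c("lat", "lon",
                                          "date_early", "date_late")])
  x$flagged <- occ[flag]
  x
}

#' @export
print.asn_assemblage <- function(x, ...) {
  cat("Archaeological assemblage (", x$mode, " mode)\n", sep = "")
  cat("  ", nrow(x$values), " occupations x ", ncol(x$values),
      " traits\n", sep = "")
  cat("  cultures:",
      paste(sort(unique(as.character(x$meta$culture))), collapse = ", "),
      "\n")
  if (length(x$flagged)) {
    cat("  flagged (missing coordinates/dates):",
        paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default column mapping for assemblage tables
#'
#' Maps the package's canonical field names to the column headers used in an
#' input spreadsheet. Trait columns default to every column not claimed by a
#' metadata field.
#'
#' @param occupation,site,culture,lat,lon,date_early,date_late,sequences
#'   column names in the input file.
#' @param traits character vector of trait column names, or `NULL` to use all
#'   remaining columns.
#' @return A named list usable as the `schema` argument of
#'   [read_assemblage()].
#' @export
asn_schema <- function(occupation = "occupation", site = "site",
                       culture = "culture", lat = "lat", lon = "lon",
                       date_early = "date_early", date_late = "date_late",
                       sequences = "sequences", traits = NULL) {
  list(occupation = occupation, site = site, culture = culture,
       lat = lat, lon = lon, date_early = date_early,
       date_late = date_late, sequences = sequences, traits = traits)
}

#' Read an occupation-by-trait table from CSV or XLSX
#'
#' Reads a flat table with one row per occupation: metadata columns (see
#' [asn_schema()]) plus one numeric column per trait. Rows with missing
#' coordinates or dates are loaded and flagged, never silently dropped; the
#' returned object carries a load report in `attr(x, "load_report")`.
#'
#' @param path file path; `.xlsx` files are read with the readxl package
#'   (worksheet chosen by `sheet`), anything else as UTF-8 CSV.
#' @param mode `"counts"` or `"presence"`.
#' @param schema column mapping from [asn_schema()].
#' @param sheet worksheet name or index for XLSX input.
#' @param date_bounds passed to [asn_assemblage()].
#' @return An [asn_assemblage()] object.
#' @export
read_assemblage <- function(path, mode = c("counts", "presence"),
                            schema = asn_schema(), sheet = 1,
                            date_bounds = c(6000, 9000)) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    tab <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  meta_fields <- c("occupation", "site", "culture", "lat", "lon",
                   "date_early", "date_late", "sequences")
  mapped <- unlist(schema[meta_fields])
  missing_cols <- mapped[!mapped %in% names(tab)]
  if (length(missing_cols)) {
    stop("input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  meta <- data.frame(
    occupation = as.character(tab[[schema$occupation]]),
    site = as.character(tab[[schema$site]]),
    culture = as.character(tab[[schema$culture]]),
    lat = as.numeric(tab[[schema$lat]]),
    lon = as.numeric(tab[[schema$lon]]),
    date_early = as.numeric(tab[[schema$date_early]]),
    date_late = as.numeric(tab[[schema$date_late]]),
    stringsAsFactors = FALSE
  )
  meta$sequences <- parse_sequences(tab[[schema$sequences]])
  trait_cols <- schema$traits
  if (is.null(trait_cols)) trait_cols <- setdiff(names(tab), mapped)
  if (length(trait_cols) == 0L) stop("no trait columns found", call. = FALSE)
  values <- as.matrix(tab[, trait_cols, drop = FALSE])
  storage.mode(values) <- "numeric"
  rownames(values) <- meta$occupation
  x <- asn_assemblage(meta, values, mode = mode, date_bounds = date_bounds)
  attr(x, "load_report") <- data.frame(
    occupation = meta$occupation,
    loaded = TRUE,
    flagged = meta$occupation %in% x$flagged,
    stringsAsFactors = FALSE
  )
  x
}

#' Write an assemblage back to the flat CSV schema
#'
#' Inverse of [read_assemblage()] for CSV output; `read_assemblage()` on the
#' written file reproduces the assemblage.
#'
#' @param x an [asn_assemblage()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assemblage <- function(x, path) {
  stopifnot(inherits(x, "asn_assemblage"))
  meta <- x$meta
  out <- data.frame(
    occupation = meta$occupation, site = meta$site, culture = meta$culture,
    lat = meta$lat, lon = meta$lon,
    date_early = meta$date_early, date_late = meta$date_late,
    sequences = vapply(meta$sequences, paste, "", collapse = ";"),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  out <- cbind(out, as.data.frame(x$values, check.names = FALSE))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Subset an assemblage by occupation
#' @param x an [asn_assemblage()].
#' @param keep character vector of occupation IDs or logical/integer index.
#' @return The subset [asn_assemblage()].
#' @export
subset_assemblage <- function(x, keep) {
  stopifnot(inherits(x, "asn_assemblage"))
  if (is.character(keep)) keep <- match(keep, x$meta$occupation)
  meta <- x$meta[keep, , drop = FALSE]
  rownames(meta) <- NULL
  asn_assemblage(meta, x$values[keep, , drop = FALSE], mode = x$mode,
                 date_bounds = NULL)
}
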