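#' Great-circle distance between coordinate pairs
#'
#' Haversine great-circle distance on a sphere of radius 6371 km, the
#' standard choice for site-to-site distances at the scale of the Western
#' Mediterranean.
#'
#' @param lat1,lon1,lat2,lon2 decimal degrees (WGS84); vectorized.
#' @return distance(s) in km.
#' @export
#' @examples
#' great_circle_km(0, 0, 0, 180) # half the Earth's circumference
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  ok <- function(lat, lon) {
    all(!is.na(lat)) && all(!is.na(lon)) &&
      all(abs(lat) <= 90) && all(abs(lon) <= 180)
  }
  if (!ok(lat1, lon1) || !ok(lat2, lon2)) {
    stop("invalid coordinates", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Pairwise geographic distance matrix
#'
#' @param x an [asn_assemblage()] (uses its `lat`/`lon` metadata), or a
#'   data.frame with `occupation`, `lat`, `lon` columns.
#' @return symmetric matrix of great-circle distances in km, zero diagonal,
#'   dimnames the occupation IDs.
#' @export
geo_distance_matrix <- function(x) {
  meta <- if (inherits(x, "asn_assemblage")) x$meta else x
  if (anyNA(meta$lat) || anyNA(meta$lon)) {
    bad <- meta$occupation[is.na(meta$lat) | is.na(meta$lon)]
    stop("missing coordinates for occupation(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(meta)
  D <- matrix(0, n, n, dimnames = list(meta$occupation, meta$occupation))
  idx <- which(lower.tri(D), arr.ind = TRUE)
  d <- great_circle_km(meta$lat[idx[, 1L]], meta$lon[idx[, 1L]],
                       meta$lat[idx[, 2L]], meta$lon[idx[, 2L]])
  D[idx] <- d
  D[idx[, c(2L, 1L), drop = FALSE]] <- d
  D
}

#' Chronological distance between two date ranges
#'
#' Occupations are dated by a calibrated range `[date_late, date_early]` in
#' cal BP. Several one-number summaries of the separation between two such
#' ranges are offered:
#' \describe{
#'   \item{`euclidean2d`}{Euclidean distance between the (early, late)
#'     range vectors, divided by `sqrt(2)` so that two ranges offset by a
#'     constant `d` years are `d` years apart (the default).}
#'   \item{`euclidean`}{the raw 2-D Euclidean distance, no rescaling.}
#'   \item{`gap`}{0 when the ranges overlap, otherwise the separation
#'     between them.}
#'   \item{`midpoint`}{absolute difference of range midpoints.}
#' }
#'
#' @param early1,late1,early2,late2 cal BP dates; vectorized.
#' @param method distance definition, see Details.
#' @return chronological distance(s) in years.
#' @export
#' @examples
#' chrono_distance(7900, 7700, 7700, 7500) # 200
chrono_distance <- function(early1, late1, early2, late2,
                            method = c("euclidean2d", "euclidean", "gap",
                                       "midpoint")) {
  method <- match.arg(method)
  if (any(early1 < late1, na.rm = TRUE) ||
      any(early2 < late2, na.rm = TRUE)) {
    stop("date_early must be >= date_late (cal BP)", call. = FALSE)
  }
  switch(method,
    euclidean2d = sqrt((early1 - early2)^2 + (late1 - late2)^2) / sqrt(2),
    euclidean = sqrt((early1 - early2)^2 + (late1 - late2)^2),
    gap = pmax(pmax(late1, late2) - pmin(early1, early2), 0),
    midpoint = abs((early1 + late1) / 2 - (early2 + late2) / 2)
  )
}

#' Pairwise chronological distance matrix
#'
#' @param x an [asn_assemblage()] or a data.frame with `occupation`,
#'   `date_early`, `date_late`.
#' @param method passed to [chrono_distance()].
#' @return symmetric matrix in years, zero diagonal.
#' @export
chrono_distance_matrix <- function(x, method = "euclidean2d") {
  meta <- if (inherits(x, "asn_assemblage")) x$meta else x
  if (anyNA(meta$date_early) || anyNA(meta$date_late)) {
    bad <- meta$occupation[is.na(meta$date_early) | is.na(meta$date_late)]
    stop("missing dates for occupation(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(meta)
  e <- meta$date_early
  l <- meta$date_late
  D <- matrix(0, n, n, dimnames = list(meta$occupation, meta$occupation))
  idx <- which(lower.tri(D), arr.ind = TRUE)
  d <- chrono_distance(e[idx[, 1L]], l[idx[, 1L]],
                       e[idx[, 2L]], l[idx[, 2L]], method = method)
  D[idx] <- d
  D[idx[, c(2L, 1L), drop = FALSE]] <- d
  D
}

#' Paired geographic and chronological distance matrices
#'
#' @param x an [asn_assemblage()].
#' @param chrono_method passed to [chrono_distance()].
#' @return An `asn_distances` object: list with `geo_km`, `chrono_years`,
#'   and the chronological `method`.
#' @export
distance_matrices <- function(x, chrono_method = "euclidean2d") {
  structure(
    list(geo_km = geo_distance_matrix(x),
         chrono_years = chrono_distance_matrix(x, method = chrono_method),
         method = chrono_method),
    class = "asn_distances"
  )
}

#' Default time-sequence windows
#'
#' The three Early Neolithic sequences used for time-sequential networks:
#' the pioneer phase (8000-7600 cal BP), the expansion and diversification
#' phase (7650-6800 cal BP), and the final Early Neolithic (7000-6500 cal
#' BP). Note that consecutive windows deliberately overlap.
#'
#' @return data.frame with columns `id`, `start` (older bound, cal BP) and
#'   `end` (younger bound).
#' @export
sequence_windows <- function() {
  data.frame(id = 1:3,
             start = c(8000, 7650, 7000),
             end = c(7600, 6800, 6500))
}

#' Assign occupations to time sequences
#'
#' Membership is by closed-interval overlap between the occupation's date
#' range and each sequence window. A curated label (from the source dataset)
#' always takes precedence over the date-derived assignment, because the
#' overlapping window bounds make date-only assignment non-unique.
#'
#' @param date_early,date_late cal BP dates (vectorized).
#' @param windows a window table as from [sequence_windows()].
#' @param curated optional list of integer vectors (or character like
#'   `"1;2"`); non-empty entries are returned verbatim.
#' @return list of integer vectors, one per occupation.
#' @export
#' @examples
#' assign_sequences(7900, 7700) # window 1 only
assign_sequences <- function(date_early, date_late,
                             windows = sequence_windows(), curated = NULL) {
  n <- length(date_early)
  stopifnot(length(date_late) == n)
  if (is.character(curated)) curated <- parse_sequences(curated)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.null(curated) && length(curated[[i]]) > 0L) {
      out[[i]] <- sort(unique(as.integer(curated[[i]])))
      next
    }
    e <- date_early[i]
    l <- date_late[i]
    if (is.na(e) || is.na(l)) {
      stop("occupation ", i, " has no dates and no curated sequence label",
           call. = FALSE)
    }
    hit <- windows$id[e >= windows$end & l <= windows$start]
    if (length(hit) == 0L) {
      stop("occupation ", i, " (", e, "-", l,
           " cal BP) overlaps no sequence window", call. = FALSE)
    }
    out[[i]] <- sort(unique(as.integer(hit)))
  }
  out
}

#' Subset an assemblage to a consecutive pair of time sequences
#'
#' Keeps every occupation whose sequence membership intersects the pair
#' (sequences 1-2 or 2-3); downstream similarity, thresholding and
#' statistics operate unchanged on the subset.
#'
#' @param x an [asn_assemblage()] with assigned `sequences`.
#' @param pair `"12"` or `"23"`.
#' @return The subset [asn_assemblage()].
#' @export
sequence_pair_subset <- function(x, pair = c("12", "23")) {
  pair <- match.arg(as.character(pair), c("12", "23"))
  wanted <- if (pair == "12") c(1L, 2L) else c(2L, 3L)
  stopifnot(inherits(x, "asn_assemblage"))
  keep <- vapply(x$meta$sequences,
                 function(s) length(intersect(s, wanted)) > 0L, logical(1))
  if (!any(keep)) {
    stop("no occupations fall in sequence pair ", pair, call. = FALSE)
  }
  subset_assemblage(x, which(keep))
}
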