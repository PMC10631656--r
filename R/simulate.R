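#' Configuration for the synthetic assemblage generator
#'
#' Describes a study region with `n_cultures` cultural units, each with its
#' own trait-frequency profile (drawn from a symmetric Dirichlet whose
#' concentration controls between-culture divergence: small values give
#' well-separated profiles), a spatial center, and a preference among the
#' time-sequence windows. Occupations scatter around their culture's center,
#' draw a dated range inside a weighted window, and sample traits from their
#' culture's profile — optionally blended towards geographically close
#' cultures (`distance_decay_strength > 0` plants an isolation-by-distance
#' signal).
#'
#' @param n_cultures number of cultural units.
#' @param occupations_per_culture occupations per unit.
#' @param n_traits number of trait types; `NULL` resolves at simulation to
#'   11 for counts (decorative techniques) and 88 for presence (bead types).
#' @param trait_profile_concentration symmetric Dirichlet concentration for
#'   culture profiles; smaller = more divergent cultures.
#' @param counts_per_occupation multinomial total per occupation (counts
#'   mode).
#' @param presence_base_rate baseline per-trait presence probability.
#' @param culture_effect added presence probability for a culture's own
#'   trait pool.
#' @param spatial_centers data.frame with `lat`, `lon`, one row per
#'   culture; `NULL` for evenly spaced centers along the north-western
#'   Mediterranean arc.
#' @param dispersion_km spatial scatter (km) of occupations around their
#'   center.
#' @param sequence_windows window table as [sequence_windows()].
#' @param window_weights `n_cultures` x `n_windows` matrix of window choice
#'   weights; `NULL` ties culture k to period k when the counts match,
#'   otherwise uniform.
#' @param distance_decay_strength in \[0, 1\]: how strongly an occupation's
#'   trait profile is pulled towards a distance-weighted blend of all
#'   culture profiles (0 = pure culture profile).
#' @param decay_length_km e-folding length of the distance weighting.
#' @param date_span_years range of occupation durations (years).
#' @param seed RNG seed; a fixed seed reproduces the dataset exactly.
#' @return An `asn_sim_config` list.
#' @export
sim_config <- function(n_cultures = 3,
                       occupations_per_culture = 12,
                       n_traits = NULL,
                       trait_profile_concentration = 0.5,
                       counts_per_occupation = 200,
                       presence_base_rate = 0.05,
                       culture_effect = 0.35,
                       spatial_centers = NULL,
                       dispersion_km = 120,
                       sequence_windows = asnet::sequence_windows(),
                       window_weights = NULL,
                       distance_decay_strength = 0,
                       decay_length_km = 300,
                       date_span_years = c(150, 350),
                       seed = 1L) {
  stopifnot(n_cultures >= 1, occupations_per_culture >= 1,
            trait_profile_concentration > 0, counts_per_occupation >= 1,
            presence_base_rate >= 0, presence_base_rate <= 1,
            culture_effect >= 0, presence_base_rate + culture_effect <= 1,
            dispersion_km > 0, distance_decay_strength >= 0,
            distance_decay_strength <= 1, decay_length_km > 0)
  if (is.null(spatial_centers)) {
    lon <- seq(-1, 9, length.out = max(n_cultures, 2))[seq_len(n_cultures)]
    spatial_centers <- data.frame(lat = 42.5 + 1.5 * cos(lon / 4), lon = lon)
  }
  stopifnot(nrow(spatial_centers) == n_cultures)
  structure(
    list(n_cultures = n_cultures,
         occupations_per_culture = occupations_per_culture,
         n_traits = n_traits,
         trait_profile_concentration = trait_profile_concentration,
         counts_per_occupation = counts_per_occupation,
         presence_base_rate = presence_base_rate,
         culture_effect = culture_effect,
         spatial_centers = spatial_centers,
         dispersion_km = dispersion_km,
         sequence_windows = sequence_windows,
         window_weights = window_weights,
         distance_decay_strength = distance_decay_strength,
         decay_length_km = decay_length_km,
         date_span_years = date_span_years,
         seed = as.integer(seed)),
    class = "asn_sim_config"
  )
}

#' @noRd
rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha)
  while (sum(g) <= 0) g <- rgamma(k, shape = alpha) # numeric underflow guard
  g / sum(g)
}

#' Simulate a schema-compatible assemblage with planted structure
#'
#' Generates an [asn_assemblage()] that passes all input validation and has
#' known ground truth: culture labels, spatial centers, window membership,
#' and (optionally) a planted distance-decay in trait frequencies. In
#' presence mode each trait type belongs to one culture's pool (round
#' robin), emulating mutually exclusive bead types: a culture's own traits
#' are present with probability `base + effect`, foreign traits with
#' `base`.
#'
#' @param config an [sim_config()].
#' @param mode `"counts"` or `"presence"`.
#' @return An [asn_assemblage()]; planted culture labels sit in
#'   `meta$culture` (`"CU1"`, `"CU2"`, ...).
#' @export
#' @examples
#' a <- simulate_assemblage(sim_config(seed = 42), mode = "counts")
#' a
simulate_assemblage <- function(config, mode = c("counts", "presence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "asn_sim_config"))
  k <- config$n_cultures
  m <- config$occupations_per_culture
  n <- k * m
  n_traits <- config$n_traits
  if (is.null(n_traits)) n_traits <- if (mode == "counts") 11L else 88L
  if (n_traits < 1L || n < 1L) stop("infeasible configuration", call. = FALSE)
  set.seed(config$seed)

  profiles <- t(vapply(seq_len(k), function(i) {
    rdirichlet1(n_traits, config$trait_profile_concentration)
  }, numeric(n_traits)))

  culture <- rep(seq_len(k), each = m)
  centers <- config$spatial_centers
  theta <- runif(n, 0, 2 * pi)
  rad <- abs(rnorm(n, 0, config$dispersion_km))
  lat <- centers$lat[culture] + rad * cos(theta) / 111.32
  lon <- centers$lon[culture] +
    rad * sin(theta) / (111.32 * cos(centers$lat[culture] * pi / 180))

  win <- config$sequence_windows
  ww <- config$window_weights
  if (is.null(ww)) {
    ww <- matrix(1, k, nrow(win))
    if (k == nrow(win)) ww <- ww * 0.15 + diag(nrow(win)) * 0.7
  }
  which_win <- vapply(culture, function(cu) {
    sample.int(nrow(win), 1L, prob = ww[cu, ])
  }, integer(1))
  span <- runif(n, config$date_span_years[1L], config$date_span_years[2L])
  mid <- runif(n, win$end[which_win], win$start[which_win])
  date_early <- round(pmin(mid + span / 2, 9000))
  date_late <- round(pmax(mid - span / 2, 6000))

  if (mode == "counts") {
    s <- config$distance_decay_strength
    values <- matrix(0L, n, n_traits)
    for (i in seq_len(n)) {
      p <- profiles[culture[i], ]
      if (s > 0) {
        d <- great_circle_km(lat[i], lon[i], centers$lat, centers$lon)
        wgt <- exp(-d / config$decay_length_km)
        blend <- colSums(profiles * (wgt / sum(wgt)))
        p <- (1 - s) * p + s * blend
      }
      values[i, ] <- rmultinom(1L, config$counts_per_occupation, p)
    }
    # multinomial totals are positive, so row sums are positive
  } else {
    home <- rep_len(seq_len(k), n_traits)
    values <- matrix(0L, n, n_traits)
    for (i in seq_len(n)) {
      p <- config$presence_base_rate +
        config$culture_effect * (home == culture[i])
      row <- rbinom(n_traits, 1L, p)
      if (sum(row) == 0L) row[which.max(p)] <- 1L # no empty assemblages
      values[i, ] <- row
    }
  }
  prefix <- if (mode == "counts") "SYC" else "SYO"
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  colnames(values) <- sprintf("trait_%02d", seq_len(n_traits))
  rownames(values) <- ids
  meta <- data.frame(
    occupation = ids,
    site = sprintf("Synthetic site %02d", seq_len(n)),
    culture = sprintf("CU%d", culture),
    lat = lat, lon = lon,
    date_early = date_early, date_late = date_late,
    stringsAsFactors = FALSE
  )
  meta$sequences <- assign_sequences(date_early, date_late,
                                     windows = config$sequence_windows)
  asn_assemblage(meta, values, mode = mode, date_bounds = c(6000, 9000))
}

#' Parameter-recovery experiment on synthetic data
#'
#' Runs the full analysis on one simulated dataset and reports how well the
#' planted structure is recovered: label assortativity of the threshold
#' network's edges with the planted cultures, the full-matrix Mantel
#' correlation of cultural against geographic distance (the planted
#' isolation-by-distance signal), and per-culture versus global density.
#'
#' @param config an [sim_config()].
#' @param mode `"counts"` or `"presence"`.
#' @param max_outliers passed to [connectivity_threshold()].
#' @param permutations Mantel permutations.
#' @return list with `threshold`, `network`, `assortativity`,
#'   `mantel_geo` (an `asn_mantel`), `global_density`, `unit_densities`,
#'   and `within_between_gap` (mean within-culture minus mean
#'   between-culture similarity).
#' @export
recovery_experiment <- function(config, mode = "counts", max_outliers = 0,
                                permutations = 199) {
  a <- simulate_assemblage(config, mode = mode)
  S <- similarity_matrix(a)
  thr <- connectivity_threshold(S, max_outliers = max_outliers)
  g <- build_asn(S, thr, meta = a)
  cult <- igraph::V(g)$culture
  assort <- if (length(unique(cult)) > 1L) {
    igraph::assortativity_nominal(g, as.integer(factor(cult)))
  } else NA_real_
  D <- distance_matrices(a)
  mg <- mantel_test(cultural_distance(S), D$geo_km,
                    permutations = permutations, seed = config$seed)
  units <- sort(unique(cult))
  ud <- vapply(units, function(u) {
    tryCatch(unit_stats(g, u)$density, error = function(e) NA_real_)
  }, numeric(1))
  same <- outer(a$meta$culture, a$meta$culture, "==")
  lt <- lower.tri(S$S)
  gap <- mean(S$S[lt & same]) - mean(S$S[lt & !same])
  list(threshold = as.numeric(thr), network = g, assortativity = assort,
       mantel_geo = mg, global_density = asn_density(g),
       unit_densities = ud, within_between_gap = gap)
}
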