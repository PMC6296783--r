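#' Basal soil respiration from an hourly O2-consumption series
#'
#' Mean O2-consumption rate over a late, stable window of a 24-h basal
#' (no substrate added) measurement. The default window is hours 14 to 24
#' inclusive (11 readings).
#'
#' @param series A [respiration_series()] (basal run) or a numeric vector
#'   of hourly rates, hour 1 first.
#' @param window Integer vector `c(first, last)` of the averaging window,
#'   1-based and inclusive.
#' @return Mean rate over the window (ul O2 h^-1 g^-1 dry soil).
#' @examples
#' basal_respiration(respiration_series(1:24))  # mean of 14..24 = 19
#' @export
basal_respiration <- function(series, window = c(14L, 24L)) {
  rates <- .series_rates(series, glucose_expected = FALSE)
  stopifnot(length(window) == 2L, window[1L] >= 1L, window[2L] >= window[1L])
  if (length(rates) < window[2L])
    stop("incomplete series: need at least ", window[2L],
         " hourly readings, got ", length(rates), call. = FALSE)
  mean(rates[window[1L]:window[2L]])
}

#' Maximum initial respiratory response (MIRR)
#'
#' The mean of the three lowest hourly readings within the first 10 h of
#' a substrate-induced (glucose) run - i.e. the respiratory plateau
#' between the initial disturbance peak and the microbial growth peak.
#'
#' @param series A [respiration_series()] (glucose run) or numeric vector
#'   of hourly rates.
#' @param window_hours Length of the initial search window (default 10).
#' @param n_lowest Number of lowest readings averaged (default 3).
#' @return MIRR (ul O2 g^-1 dry soil h^-1).
#' @examples
#' compute_mirr(respiration_series(c(5, 4, 3, 2, 1, 6, 7, 8, 9, 10), TRUE))  # 2
#' @export
compute_mirr <- function(series, window_hours = 10L, n_lowest = 3L) {
  rates <- .series_rates(series, glucose_expected = TRUE)
  if (length(rates) < window_hours)
    stop("incomplete series: need at least ", window_hours,
         " hourly readings, got ", length(rates), call. = FALSE)
  window <- rates[seq_len(window_hours)]
  if (length(window) < n_lowest)
    stop("fewer than ", n_lowest, " readings in the search window",
         call. = FALSE)
  mean(sort(window)[seq_len(n_lowest)])
}

.series_rates <- function(series, glucose_expected) {
  if (inherits(series, "respiration_series")) {
    if (!identical(series$glucose, glucose_expected))
      warning(if (glucose_expected)
        "MIRR expects a glucose (substrate-induced) run" else
        "basal respiration expects a run without glucose", call. = FALSE)
    series$rates
  } else {
    stopifnot(is.numeric(series), all(is.finite(series)), all(series >= 0))
    as.numeric(series)
  }
}

#' Soil microbial biomass C from substrate-induced respiration
#'
#' Converts the maximum initial respiratory response to microbial biomass
#' carbon with the standard substrate-induced-respiration factor:
#' `biomass = 38 * MIRR` (ug C g^-1 dry soil for MIRR in
#' ul O2 g^-1 h^-1).
#'
#' @param mirr MIRR value(s), >= 0.
#' @param sir_factor Conversion factor (default 38).
#' @return Microbial biomass C (ug C g^-1 dry soil).
#' @export
microbial_biomass_c <- function(mirr, sir_factor = 38) {
  if (any(!is.finite(mirr)) || any(mirr < 0))
    stop("MIRR must be nonnegative", call. = FALSE)
  sir_factor * mirr
}

#' Water-stable aggregate fraction from wet sieving
#'
#' The fraction of water-stable aggregates of a sieved soil sample,
#' corrected for coarse matter:
#' `(water-stable fraction - coarse matter) / (initial mass - coarse matter)`,
#' with 4.0 g initial dry soil by default.
#'
#' @param water_stable_fraction Mass (g) retained as the water-stable
#'   fraction (including coarse matter).
#' @param coarse_matter Mass (g) of coarse matter (debris) in the
#'   water-stable fraction.
#' @param initial_mass Initial dry-soil mass (g), default 4.0.
#' @return Fraction in \[0, 1\]. All arguments are vectorized.
#' @examples
#' wsa_fraction(2.5, 0.5)  # 2 / 3.5
#' @export
wsa_fraction <- function(water_stable_fraction, coarse_matter,
                         initial_mass = 4.0) {
  stopifnot(all(is.finite(water_stable_fraction)), all(is.finite(coarse_matter)),
            all(water_stable_fraction >= 0), all(coarse_matter >= 0))
  if (any(coarse_matter >= initial_mass))
    stop("degenerate sample: coarse matter >= initial mass", call. = FALSE)
  if (any(water_stable_fraction < coarse_matter))
    stop("water-stable fraction below coarse matter gives a negative ",
         "aggregate fraction", call. = FALSE)
  if (any(water_stable_fraction > initial_mass))
    stop("water-stable fraction exceeds initial mass", call. = FALSE)
  (water_stable_fraction - coarse_matter) / (initial_mass - coarse_matter)
}

#' Plot-level water-stable aggregates from duplicate sievings
#'
#' Computes the aggregate fraction per duplicate and then averages the
#' duplicates of each plot (so each duplicate keeps its own denominator).
#'
#' @param sieving Data frame with columns `plot_id`, `duplicate`, `wsf_g`
#'   (water-stable fraction mass), `coarse_g` (coarse matter mass).
#' @param initial_mass Initial dry-soil mass per duplicate (g).
#' @return A data frame with columns `plot_id` and `wsa`.
#' @export
wsa_from_sieving <- function(sieving, initial_mass = 4.0) {
  stopifnot(all(c("plot_id", "duplicate", "wsf_g", "coarse_g") %in%
                names(sieving)))
  frac <- wsa_fraction(sieving$wsf_g, sieving$coarse_g, initial_mass)
  agg <- stats::aggregate(frac, by = list(plot_id = sieving$plot_id), FUN = mean)
  names(agg)[2L] <- "wsa"
  agg
}
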