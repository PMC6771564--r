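#' Ergodic age distribution of a binary-fission population
#'
#' In an exponentially growing population dividing by binary fission, young
#' cells outnumber old ones: at steady state the cumulative fraction of the
#' population younger than progress `x` through the unit cell cycle is
#' \deqn{\Phi(x) = 2 - 2^{1-x},}
#' with density \eqn{\phi(x) = 2\ln 2\, 2^{-x}}. `age_cdf()` evaluates
#' \eqn{\Phi}, `age_density()` its density, and `progress_from_fraction()`
#' the inverse \eqn{x = 1 - \log_2(2 - F)}. The inverse is the basis of both
#' the snapshot timing estimator ([marker_window()]) and inverse-transform
#' sampling of initial ages in the simulator ([init_population()]).
#'
#' @param x Progress through the unit cycle, in `[0, 1]`.
#' @return `age_cdf()`: cumulative population fraction in `[0, 1]`.
#' @examples
#' age_cdf(0.5)                    # 0.5857864
#' progress_from_fraction(age_cdf(0.3))  # 0.3
#' @export
age_cdf <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("progress must lie in [0, 1]")
  2 - 2^(1 - x)
}

#' @rdname age_cdf
#' @export
age_density <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("progress must lie in [0, 1]")
  2 * log(2) * 2^(-x)
}

#' @rdname age_cdf
#' @param F Cumulative population fraction, in `[0, 1]`.
#' @return `progress_from_fraction()`: the progress `x` with `age_cdf(x) = F`.
#' @export
progress_from_fraction <- function(F) {
  stopifnot(is.numeric(F))
  if (any(F < 0 | F > 1, na.rm = TRUE)) stop("fraction must lie in [0, 1]")
  1 - log2(2 - F)
}

#' Marker count table
#'
#' Records how many cells of the unmarked-looking `1F1K1N` category carried a
#' short-lived inheritance marker, against the total number of cells of all
#' categories counted in the same sample. `daughters_marked` states how many
#' of the two daughters born at each division carry the marker (1 for either
#' flagella-connector-remnant marker, since each remnant segregates to
#' exactly one daughter).
#'
#' @param marker Marker name (informational).
#' @param n_marked Count of `1F1K1N` cells bearing the marker.
#' @param N_total Total cells of all categories counted in the same sample.
#' @param daughters_marked How many of the two daughters carry the marker
#'   (1 or 2).
#' @return An object of class `marker_count_table`.
#' @export
marker_count_table <- function(marker, n_marked, N_total,
                               daughters_marked = 1L) {
  stopifnot(length(n_marked) == 1L, length(N_total) == 1L,
            is.numeric(n_marked), is.numeric(N_total))
  if (n_marked < 0 || n_marked > N_total) {
    stop("need 0 <= n_marked <= N_total")
  }
  if (N_total <= 0) stop("N_total must be positive")
  if (!daughters_marked %in% c(1L, 2L)) {
    stop("daughters_marked must be 1 or 2")
  }
  structure(list(marker = as.character(marker),
                 n_marked = as.numeric(n_marked),
                 N_total = as.numeric(N_total),
                 daughters_marked = as.integer(daughters_marked)),
            class = "marker_count_table")
}

#' Marker persistence window from a population snapshot
#'
#' Converts the count of marker-positive `1F1K1N` cells in a single
#' asynchronous snapshot into the real-time window for which the marker
#' persists after cytokinesis. Because only `daughters_marked` of the two
#' cells born at each division carry the marker, the observed fraction
#' `n_marked / N_total` is first scaled to the effective cumulative
#' population fraction `F_eff = (2 / daughters_marked) * n_marked / N_total`;
#' the window in cycle units is then `progress_from_fraction(F_eff)` and is
#' converted to minutes with the unit-cycle duration.
#'
#' With the published counts (22 and 7 marked cells among 515 counted, one
#' marked daughter per division, 8.9 h per unit cycle) this yields windows
#' of about 34 and 11 minutes for the new- and old-flagellum remnant
#' markers respectively.
#'
#' @param counts A [marker_count_table()], or the marked count `n_marked`
#'   when `N_total` is given.
#' @param map A [cell_cycle_map()].
#' @param N_total,daughters_marked Used only when `counts` is a bare count.
#' @return An object of class `marker_window` with elements
#'   `F_eff`, `window_u` (cycle units), `window_hours`, `window_minutes`
#'   and `window_minutes_rounded` (nearest minute, mirroring the convention
#'   of reporting "~34 minutes").
#' @examples
#' marker_window(marker_count_table("N-FCR", 22, 515))  # ~34 min
#' marker_window(7, N_total = 515)                      # ~11 min
#' @export
marker_window <- function(counts, map = cell_cycle_map(), N_total = NULL,
                          daughters_marked = 1L) {
  if (!inherits(counts, "marker_count_table")) {
    if (is.null(N_total)) {
      stop("supply a marker_count_table or both n_marked and N_total")
    }
    counts <- marker_count_table("marker", counts, N_total, daughters_marked)
  }
  stopifnot(inherits(map, "cell_cycle_map"))
  F_eff <- (2 / counts$daughters_marked) * counts$n_marked / counts$N_total
  if (F_eff > 1) {
    stop(sprintf(
      "effective cumulative fraction %.3f exceeds 1; counts incompatible with %d marked daughter(s) per division",
      F_eff, counts$daughters_marked))
  }
  w_u <- progress_from_fraction(F_eff)
  if (w_u > map$b_2F) {
    warning(sprintf(
      "window %.3f u exceeds the 1F1K1N span (b_2F = %.3f u); the marker persists beyond the one-flagellum stage and the snapshot estimator's assumption is violated",
      w_u, map$b_2F))
  }
  minutes <- w_u * map$T_unit * 60
  structure(list(marker = counts$marker,
                 F_eff = F_eff,
                 window_u = w_u,
                 window_hours = w_u * map$T_unit,
                 window_minutes = minutes,
                 window_minutes_rounded = round_half_up(minutes, 0)),
            class = "marker_window")
}

#' @export
print.marker_window <- function(x, ...) {
  cat(sprintf(
    "marker_window [%s]: ~%d min post-cytokinesis (%.1f min, %.4f u; F_eff = %.4f)\n",
    x$marker, as.integer(x$window_minutes_rounded), x$window_minutes,
    x$window_u, x$F_eff))
  invisible(x)
}

#' Expected steady-state fractions of the four cell-cycle categories
#'
#' The ergodic prediction for the share of each morphological category in an
#' exponentially growing culture, from the category boundaries: consecutive
#' differences of [age_cdf()] at `b_2F`, `b_2K`, `b_2N`.
#'
#' @param map A [cell_cycle_map()].
#' @return Named numeric vector over the four categories, summing to 1.
#' @export
expected_stage_fractions <- function(map = cell_cycle_map()) {
  stopifnot(inherits(map, "cell_cycle_map"))
  cum <- age_cdf(c(map$b_2F, map$b_2K, map$b_2N))
  setNames(c(cum[1], diff(cum), 1 - cum[3]), stage_levels())
}

# Half-up decimal rounding (base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
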