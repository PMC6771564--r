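#' Cell-cycle category boundaries on the unit cell cycle
#'
#' A `cell_cycle_map` places the three morphological transitions of the
#' procyclic trypanosome cell cycle on the unit cycle (progress `u`, 0 at
#' birth, 1 at division) and records the real-time duration of one unit:
#' appearance of the second flagellum (`b_2F`), kinetoplast division
#' (`b_2K`) and completion of mitosis (`b_2N`). Cells are therefore
#' `1F1K1N` below `b_2F`, `2F1K1N` below `b_2K`, `2F2K1N` below `b_2N`
#' and `2F2K2N` above it. The defaults are the standard values for
#' logarithmically growing procyclic culture: boundaries at 0.596, 0.852
#' and 0.942 u with one unit equal to 8.9 h.
#'
#' @param b_2F Progress at which a second flagellum appears.
#' @param b_2K Progress at which the kinetoplast has divided.
#' @param b_2N Progress at which mitosis has completed.
#' @param T_unit Real-time duration of one unit cycle, hours.
#' @return An object of class `cell_cycle_map`.
#' @examples
#' map <- cell_cycle_map()
#' classify_stage(c(0.5, 0.7, 0.9, 0.99), map)
#' @export
cell_cycle_map <- function(b_2F = 0.596, b_2K = 0.852, b_2N = 0.942,
                           T_unit = 8.9) {
  stopifnot(is.numeric(b_2F), is.numeric(b_2K), is.numeric(b_2N),
            is.numeric(T_unit), length(b_2F) == 1L, length(b_2K) == 1L,
            length(b_2N) == 1L, length(T_unit) == 1L)
  if (!(0 < b_2F && b_2F < b_2K && b_2K < b_2N && b_2N < 1)) {
    stop("cell-cycle boundaries must satisfy 0 < b_2F < b_2K < b_2N < 1")
  }
  if (!is.finite(T_unit) || T_unit <= 0) {
    stop("T_unit must be a positive duration in hours")
  }
  structure(list(b_2F = b_2F, b_2K = b_2K, b_2N = b_2N, T_unit = T_unit),
            class = "cell_cycle_map")
}

#' @export
print.cell_cycle_map <- function(x, ...) {
  cat(sprintf(
    "cell_cycle_map: 2F at %.3f u, 2K at %.3f u, 2N at %.3f u; 1 u = %.2f h\n",
    x$b_2F, x$b_2K, x$b_2N, x$T_unit))
  invisible(x)
}

stage_levels <- function() c("1F1K1N", "2F1K1N", "2F2K1N", "2F2K2N")

#' Classify cell-cycle progress into an F/K/N category
#'
#' Maps unit-cycle progress to the morphological category visible by
#' microscopy, using strict less-than comparisons at each boundary:
#' `1F1K1N` for progress below `b_2F`, `2F1K1N` below `b_2K`, `2F2K1N`
#' below `b_2N`, and `2F2K2N` otherwise.
#'
#' @param progress Numeric vector of progress values in `[0, 1)`.
#' @param map A [cell_cycle_map()].
#' @return Factor with levels `1F1K1N`, `2F1K1N`, `2F2K1N`, `2F2K2N`.
#' @export
classify_stage <- function(progress, map = cell_cycle_map()) {
  stopifnot(inherits(map, "cell_cycle_map"), is.numeric(progress))
  if (any(progress < 0 | progress >= 1, na.rm = TRUE)) {
    stop("progress must lie in [0, 1)")
  }
  idx <- 1L + (progress >= map$b_2F) + (progress >= map$b_2K) +
    (progress >= map$b_2N)
  factor(stage_levels()[idx], levels = stage_levels())
}

#' Convert cell-cycle units to hours
#'
#' @param u Numeric vector of durations in cell-cycle units.
#' @param map A [cell_cycle_map()] supplying the unit duration.
#' @return Durations in hours.
#' @examples
#' cycle_units_to_hours(c(1.24, 1.46))  # 11.0 and 13.0 h at 8.9 h/unit
#' @export
cycle_units_to_hours <- function(u, map = cell_cycle_map()) {
  stopifnot(inherits(map, "cell_cycle_map"), is.numeric(u))
  u * map$T_unit
}
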