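# Synthetic population snapshots, morphometric records and time courses.
#
# Morphometric defaults are per-cohort Gaussians anchored on published
# in-text values (anterior angles 29.5 +/- 9.3 vs 12.3 +/- 3.0 degrees;
# FAZ growing 13.2 -> 17.2 um and flagellum 20.1 -> 22.8 um over NFD G1
# re-modelling; NFD cell body ~5 um shorter). Parameters printed only as
# figure bars are synthetic fixtures chosen to honour those anchors and the
# published cohort orderings, not measured values.

default_cohort_params <- function() {
  list(
    NFD = list(
      flagellum_um = c(20.1, 1.5), cell_body_um = c(15.5, 1.5),
      faz_um = c(13.2, 1.2), kn_dist_um = c(5.5, 0.8),
      kpost_dist_um = c(4.3, 0.8), free_flagellum_um = c(6.9, 1.0),
      anterior_angle_deg = c(29.5, 9.3)),
    OFD = list(
      flagellum_um = c(22.8, 1.5), cell_body_um = c(20.5, 1.5),
      faz_um = c(17.2, 1.2), kn_dist_um = c(7.0, 0.8),
      kpost_dist_um = c(4.8, 0.8), free_flagellum_um = c(5.6, 1.0),
      anterior_angle_deg = c(12.3, 3.0)),
    NO_FCR = list(
      flagellum_um = c(22.8, 1.8), cell_body_um = c(20.5, 2.0),
      faz_um = c(17.2, 1.5), kn_dist_um = c(7.0, 1.0),
      kpost_dist_um = c(5.9, 1.0), free_flagellum_um = c(5.6, 1.2),
      anterior_angle_deg = c(12.3, 3.5))
  )
}

#' Specification of a synthetic population snapshot
#'
#' Parameters of the generator that emulates a fixed immunofluorescence
#' sample: cell ages follow the ergodic age distribution, each division
#' leaves the flagellum-tip remnant marker on exactly one daughter (the
#' new-flagellum daughter) and the mid-flagellum remnant on the other, and
#' each marker is detectable only for a short window after cytokinesis
#' (`w_tip`, `w_mid`, in cycle units). Morphometric measurements are drawn
#' from cohort-specific truncated-at-zero Gaussians.
#'
#' The default windows 0.063 and 0.020 u are the cycle-unit equivalents of
#' the ~34- and ~11-minute marker persistence times at 8.9 h per unit.
#'
#' @param n_cells Number of cells in the snapshot.
#' @param map A [cell_cycle_map()].
#' @param w_tip,w_mid Marker persistence windows (u) for the tip (NFD) and
#'   mid-flagellum (OFD) markers; must lie within the 1F1K1N span.
#' @param cohort_params Per-cohort list of `c(mean, sd)` per measurement;
#'   see `trypcycle:::default_cohort_params()`.
#' @param missing_rate Probability that any one measurement is missing.
#' @param seed Integer seed.
#' @return Object of class `snapshot_spec`.
#' @export
snapshot_spec <- function(n_cells = 515L, map = cell_cycle_map(),
                          w_tip = 0.063, w_mid = 0.020,
                          cohort_params = default_cohort_params(),
                          missing_rate = 0, seed = 1L) {
  stopifnot(n_cells >= 1, w_tip >= 0, w_mid >= 0,
            missing_rate >= 0, missing_rate <= 1)
  if (w_tip >= map$b_2F || w_mid >= map$b_2F) {
    stop("marker windows must lie within the 1F1K1N span (w < b_2F)")
  }
  structure(list(n_cells = as.integer(n_cells), map = map, w_tip = w_tip,
                 w_mid = w_mid, cohort_params = cohort_params,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "snapshot_spec")
}

rtruncnorm0 <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic population snapshot of cell records
#'
#' Draws `n_cells` records: age by inverse-transform sampling of
#' [age_cdf()]; F/K/N configuration from [classify_stage()]; for `1F1K1N`
#' cells, daughter identity (NFD or OFD with probability 1/2 each, one
#' marked daughter of each kind per division) and the corresponding marker
#' if the cell is younger than that marker's persistence window; and
#' cohort-appropriate morphometric measurements (truncated at zero;
#' `free_flagellum_um` clipped to `flagellum_um`). Cells past `1F1K1N`
#' carry neither marker and draw measurements from the no-FCR
#' distribution.
#'
#' @param spec A [snapshot_spec()].
#' @return Data frame in the cell-record schema (see
#'   [read_cell_records()]), one row per cell.
#' @export
generate_snapshot <- function(spec = snapshot_spec()) {
  stopifnot(inherits(spec, "snapshot_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  map <- spec$map
  progress <- progress_from_fraction(runif(n))
  stage <- classify_stage(progress, map)
  counts <- list("1F1K1N" = c(1, 1, 1), "2F1K1N" = c(2, 1, 1),
                 "2F2K1N" = c(2, 2, 1), "2F2K2N" = c(2, 2, 2))
  fkn <- t(vapply(as.character(stage), function(s) counts[[s]], numeric(3)))
  is_nfd_born <- runif(n) < 0.5   # which daughter of its division this cell is
  is1 <- stage == "1F1K1N"
  tip <- is1 & is_nfd_born & progress < spec$w_tip
  mid <- is1 & !is_nfd_born & progress < spec$w_mid
  cohort <- ifelse(tip, "NFD", ifelse(mid, "OFD", "NO_FCR"))
  meas <- matrix(NA_real_, n, length(measurement_columns()),
                 dimnames = list(NULL, measurement_columns()))
  for (co in c("NFD", "OFD", "NO_FCR")) {
    rows <- which(cohort == co)
    if (!length(rows)) next
    for (m in measurement_columns()) {
      p <- spec$cohort_params[[co]][[m]]
      meas[rows, m] <- rtruncnorm0(length(rows), p[1], p[2])
    }
  }
  meas[, "free_flagellum_um"] <- pmin(meas[, "free_flagellum_um"],
                                      meas[, "flagellum_um"])
  if (spec$missing_rate > 0) {
    drop <- matrix(runif(length(meas)) < spec$missing_rate, nrow(meas))
    meas[drop] <- NA_real_
  }
  out <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                    n_flagella = fkn[, 1], n_kinetoplasts = fkn[, 2],
                    n_nuclei = fkn[, 3],
                    tip_marker = as.integer(tip),
                    mid_marker = as.integer(mid),
                    meas)
  attr(out, "progress") <- progress
  out
}

#' Recover marker persistence windows from a snapshot
#'
#' Parameter-recovery harness: counts marker-positive `1F1K1N` cells
#' against the whole table and inverts the counts with [marker_window()]
#' (one marked daughter per division). On snapshots from
#' [generate_snapshot()] the estimates fall within binomial error of the
#' generating `w_tip` / `w_mid`.
#'
#' @param table Cell-record data frame.
#' @param map A [cell_cycle_map()].
#' @return List with `w_tip_est` and `w_mid_est` (cycle units) and the two
#'   underlying [marker_window()] objects.
#' @export
recover_windows <- function(table, map = cell_cycle_map()) {
  N <- nrow(table)
  cls <- classify_cohort(table)
  est <- function(n_marked, name) {
    if (n_marked == 0) {
      warning("no ", name, "-marked cells; returning a zero window")
      return(list(window_u = 0))
    }
    marker_window(marker_count_table(name, n_marked, N, 1L), map)
  }
  wt <- est(sum(cls == "NFD"), "tip")
  wm <- est(sum(cls == "OFD"), "mid")
  list(w_tip_est = wt$window_u, w_mid_est = wm$window_u,
       tip = wt, mid = wm)
}

#' Generate an observed time course by subsampling the simulator
#'
#' Emulates the counting experiment: at each requested report time of a
#' label-inheritance simulation, a fixed number of cells (default 500) is
#' drawn without replacement from the simulated population and tallied by
#' category and old-flagellum label class. Sampling category counts without
#' replacement from the population tallies is multivariate hypergeometric,
#' drawn sequentially with [stats::rhyper()].
#'
#' @param scenario A [sim_scenario()].
#' @param map A [cell_cycle_map()].
#' @param sample_size Cells counted per timepoint.
#' @param timepoints Report times (u) to sample; default all report times.
#' @param seed Seed for the subsampling (the simulation itself uses
#'   `scenario$seed`).
#' @return Data frame like a `sim_report` but with sampled counts.
#' @export
generate_timecourse <- function(scenario = sim_scenario(),
                                map = cell_cycle_map(), sample_size = 500L,
                                timepoints = NULL, seed = 1L) {
  report <- run_labelling_sim(scenario, map)
  times <- sort(unique(report$time_u))
  if (is.null(timepoints)) timepoints <- times
  if (!all(timepoints %in% times)) {
    stop("timepoints must be report times of the simulation")
  }
  set.seed(seed)
  out <- lapply(timepoints, function(tp) {
    d <- report[report$time_u == tp, ]
    total <- sum(d$count)
    if (sample_size > total) {
      stop(sprintf("sample_size %d exceeds population %d at t = %.2f",
                   sample_size, total, tp))
    }
    drawn <- integer(nrow(d))
    remaining_pop <- total
    remaining_draw <- sample_size
    for (i in seq_len(nrow(d))) {
      if (i == nrow(d)) {
        drawn[i] <- remaining_draw
      } else {
        drawn[i] <- rhyper(1, d$count[i], remaining_pop - d$count[i],
                           remaining_draw)
      }
      remaining_pop <- remaining_pop - d$count[i]
      remaining_draw <- remaining_draw - drawn[i]
    }
    d$count <- drawn
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "scenario") <- attr(report, "scenario")
  class(res) <- c("sim_report", "data.frame")
  res
}
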