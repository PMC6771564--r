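#' @name cohort_stats
#' @title Morphometric cohort statistics for 1F1K1N cells
#'
#' @description
#' One-flagellum, one-kinetoplast, one-nucleus (`1F1K1N`) cells fall into
#' three cohorts according to their flagella-connector-remnant markers: the
#' new-flagellum daughters (NFD, tip marker), the old-flagellum daughters
#' (OFD, mid-flagellum marker) and cells born long enough ago that the
#' remnant has been removed (no-FCR). These functions classify measured
#' cell records into cohorts, summarise morphometric parameters per cohort
#' and run pairwise two-sample tests between cohorts.
NULL

cohort_levels <- function() c("NFD", "OFD", "NO_FCR", "NOT_1F1K1N")

#' Measurement columns of a cell-record table
#'
#' @return Character vector of the morphometric column names (lengths in
#'   micrometres, the anterior angle in degrees).
#' @export
measurement_columns <- function() {
  c("flagellum_um", "cell_body_um", "faz_um", "kn_dist_um",
    "kpost_dist_um", "free_flagellum_um", "anterior_angle_deg")
}

#' Classify cell records into FCR cohorts
#'
#' A record is `NOT_1F1K1N` unless its flagellum/kinetoplast/nucleus counts
#' are (1, 1, 1); a `1F1K1N` record is `NFD` if the flagellum-tip marker is
#' present, `OFD` if the mid-flagellum marker is present, and `NO_FCR`
#' otherwise. Both markers on one `1F1K1N` record is a data error: the two
#' remnants segregate to different daughters.
#'
#' @param records Data frame with columns `n_flagella`, `n_kinetoplasts`,
#'   `n_nuclei`, `tip_marker`, `mid_marker` (0/1 or logical).
#' @return Factor of cohort labels, one per row.
#' @export
classify_cohort <- function(records) {
  req <- c("n_flagella", "n_kinetoplasts", "n_nuclei", "tip_marker",
           "mid_marker")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  is111 <- records$n_flagella == 1 & records$n_kinetoplasts == 1 &
    records$n_nuclei == 1
  tip <- as.logical(records$tip_marker)
  mid <- as.logical(records$mid_marker)
  both <- which(is111 & tip & mid)
  if (length(both)) {
    stop("1F1K1N record(s) with both markers present (rows ",
         paste(both, collapse = ", "),
         "): the two remnants mark different daughters")
  }
  out <- rep("NOT_1F1K1N", nrow(records))
  out[is111] <- "NO_FCR"
  out[is111 & tip] <- "NFD"
  out[is111 & mid] <- "OFD"
  factor(out, levels = cohort_levels())
}

#' Marker-positive percentage of a counted category
#'
#' Plain percentage `100 * n_pos / n_total`, rounded half-up to one decimal
#' place to match the convention of printed counts (22 of 219 -> 10.0%,
#' 10 of 136 -> 7.4%).
#'
#' @param n_pos Number of positive cells.
#' @param n_total Number of cells counted in the category.
#' @return Percentage with one decimal place.
#' @export
tally_fraction <- function(n_pos, n_total) {
  stopifnot(is.numeric(n_pos), is.numeric(n_total))
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_pos < 0 | n_pos > n_total)) stop("need 0 <= n_pos <= n_total")
  round_half_up(100 * n_pos / n_total, 1)
}

#' Per-cohort summary of one morphometric parameter
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of one
#' measurement within one cohort; missing values are excluded and counted.
#'
#' @param records Cell-record data frame.
#' @param cohort Cohort label to select (see [classify_cohort()]), or `NULL`
#'   to use all rows.
#' @param parameter Name of the measurement column.
#' @return List with `mean`, `sd`, `n` (non-missing), `n_missing`.
#' @export
summarize_cohort <- function(records, cohort = NULL, parameter) {
  if (!parameter %in% names(records)) {
    stop("unknown parameter: ", parameter)
  }
  if (!is.null(cohort)) {
    records <- records[classify_cohort(records) == cohort, , drop = FALSE]
  }
  x <- records[[parameter]]
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop("need at least 2 non-missing values to summarise '", parameter, "'")
  }
  list(mean = mean(x), sd = sd(x), n = length(x), n_missing = n_missing)
}

#' Two-sample t test from summary statistics or raw vectors
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom (default), or the pooled-variance Student test, computed from
#' per-group mean, standard deviation and size. This form is needed when
#' only the printed summaries of a measurement are available; raw vectors
#' can be passed instead via `x` and `y`, which simply forwards to
#' [stats::t.test()]-compatible summaries.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB Per-group summaries.
#' @param x,y Alternative raw data vectors (summaries are then computed).
#' @param var_equal If `TRUE`, use the pooled Student test.
#' @param alpha Significance level for the convenience flag.
#' @return List with `t`, `df`, `p`, `significant` and the method name.
#' @examples
#' # printed anterior-angle summaries: NFD 29.5 +/- 9.3 (n = 19),
#' # OFD 12.3 +/- 3.0 (n = 17)
#' two_sample_test(29.5, 9.3, 19, 12.3, 3.0, 17)
#' @export
two_sample_test <- function(meanA = NULL, sdA = NULL, nA = NULL,
                            meanB = NULL, sdB = NULL, nB = NULL,
                            x = NULL, y = NULL, var_equal = FALSE,
                            alpha = 0.05) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("supply both x and y")
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    meanA <- mean(x); sdA <- sd(x); nA <- length(x)
    meanB <- mean(y); sdB <- sd(y); nB <- length(y)
  }
  stopifnot(is.numeric(meanA), is.numeric(meanB))
  if (nA < 2 || nB < 2) stop("each group needs n >= 2")
  if (sdA < 0 || sdB < 0) stop("standard deviations must be >= 0")
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) stop("both groups constant and equal: test undefined")
    stop("both standard deviations are 0: test degenerate")
  }
  if (var_equal) {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
    method <- "Student pooled t"
  } else {
    vA <- sdA^2 / nA
    vB <- sdB^2 / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
    method <- "Welch t"
  }
  t_stat <- (meanA - meanB) / se
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, significant = p < alpha, method = method)
}

#' Left-closed histogram anchored at zero
#'
#' Bins `[0, w), [w, 2w), ...` so that counts are reproducible across
#' cohorts and parameters regardless of the data range.
#'
#' @param records Cell-record data frame (or `NULL` when `values` given).
#' @param cohort Cohort label or `NULL` for all rows.
#' @param parameter Measurement column name.
#' @param bin_width Positive bin width.
#' @param values Optional raw numeric vector, bypassing record selection.
#' @return List with `breaks` (length k + 1) and `counts` (length k);
#'   empty selections give empty vectors.
#' @export
cohort_histogram <- function(records = NULL, cohort = NULL, parameter = NULL,
                             bin_width, values = NULL) {
  stopifnot(is.numeric(bin_width), bin_width > 0)
  if (is.null(values)) {
    if (!is.null(cohort)) {
      records <- records[classify_cohort(records) == cohort, , drop = FALSE]
    }
    values <- records[[parameter]]
  }
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    return(list(breaks = numeric(0), counts = integer(0)))
  }
  if (any(values < 0)) stop("histogram is anchored at 0; negative values")
  idx <- floor(values / bin_width)
  k_max <- max(idx)
  counts <- tabulate(idx + 1L, nbins = k_max + 1L)
  list(breaks = bin_width * (0:(k_max + 1L)), counts = counts)
}

#' Full cohort summary with pairwise tests
#'
#' For each measurement column present, summarises the three `1F1K1N`
#' cohorts and tests each cohort pair; no multiple-testing correction is
#' applied (per-parameter significance at `alpha` is reported as-is).
#'
#' @param records Cell-record data frame.
#' @param parameters Measurement columns to analyse (default: all present).
#' @param var_equal Use pooled Student tests instead of Welch.
#' @param alpha Significance level.
#' @return List of two data frames: `summaries` (cohort x parameter mean,
#'   sd, n) and `tests` (pairwise t, df, p, significance).
#' @export
cohort_summary <- function(records, parameters = NULL, var_equal = FALSE,
                           alpha = 0.05) {
  if (is.null(parameters)) {
    parameters <- intersect(measurement_columns(), names(records))
  }
  cohorts <- c("NFD", "OFD", "NO_FCR")
  cls <- classify_cohort(records)
  sum_rows <- list(); test_rows <- list()
  for (p in parameters) {
    stats_by <- list()
    for (co in cohorts) {
      x <- records[[p]][cls == co]
      x <- x[!is.na(x)]
      if (length(x) >= 2L) {
        stats_by[[co]] <- list(mean = mean(x), sd = sd(x), n = length(x))
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          parameter = p, cohort = co, mean = mean(x), sd = sd(x),
          n = length(x))
      }
    }
    elig <- intersect(cohorts, names(stats_by))
    pairs <- if (length(elig) >= 2L) {
      utils::combn(elig, 2, simplify = FALSE)
    } else list()
    for (pr in pairs) {
      a <- stats_by[[pr[1]]]; b <- stats_by[[pr[2]]]
      tt <- two_sample_test(a$mean, a$sd, a$n, b$mean, b$sd, b$n,
                            var_equal = var_equal, alpha = alpha)
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        parameter = p, cohort_a = pr[1], cohort_b = pr[2],
        t = tt$t, df = tt$df, p_value = tt$p, significant = tt$significant)
    }
  }
  list(summaries = do.call(rbind, sum_rows), tests = do.call(rbind, test_rows))
}
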