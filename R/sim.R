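# Agent-based simulation of flagellum-label inheritance under RNAi.
#
# Agents are held as parallel vectors (structure-of-arrays) for speed:
#   progress  numeric, unit-cycle progress in [0, 1)
#   old_label integer, label state of the old flagellum
#   new_label integer, label state of the new flagellum (NONE below b_2F)
#   inheritance integer, which flagellum the cell inherited at its birth

LABEL_NONE <- 0L
LABEL_FULL <- 1L
LABEL_PARTIAL <- 2L
LABEL_UNLABELLED <- 3L
INH_OFD <- 1L
INH_NFD <- 2L

label_names <- function() c("FULL", "PARTIAL", "UNLABELLED")

#' Simulation scenario for the label-inheritance model
#'
#' Bundles the parameters of the agent-based eYFP label-dilution model. The
#' defaults are the modelled culture conditions: about 10,000 agents stepped
#' at 0.01 u, RNAi becoming effective at 0.3 u, reports every 0.05 u, and a
#' total duration long enough to cover the plateau window 1.24-1.46 u after
#' induction. Unequal per-step increments for the two inheritance classes
#' express a slower cell cycle in one daughter class: `increment_nfd = 0.009`
#' against `increment_ofd = 0.01` makes the new-flagellum daughter's cycle
#' ~10% longer, and vice versa.
#'
#' @param n_agents Number of agents at time 0.
#' @param dt Global step size in cycle units.
#' @param induction_time Time (u) at which RNAi becomes effective.
#' @param increment_ofd,increment_nfd Per-step progress increments (u) for
#'   cells that inherited the old or the new flagellum.
#' @param report_interval Interval (u) between population reports.
#' @param duration Total simulated time (u); must extend at least 1.46 u
#'   beyond induction so the plateau window is observable.
#' @param seed Integer seed; the whole run uses one seeded generator.
#' @param init_inheritance `"random"` (each initial agent OFD or NFD with
#'   probability 1/2, the steady state of a process producing one of each
#'   per division) or `"alternating"`.
#' @return An object of class `sim_scenario`.
#' @examples
#' sim_scenario()                     # equal rates
#' sim_scenario(increment_nfd = 0.009)  # NFD cycle ~10% longer
#' @export
sim_scenario <- function(n_agents = 10000L, dt = 0.01, induction_time = 0.3,
                         increment_ofd = 0.01, increment_nfd = 0.01,
                         report_interval = 0.05, duration = 1.8,
                         seed = 1L, init_inheritance = c("random", "alternating")) {
  init_inheritance <- match.arg(init_inheritance)
  stopifnot(n_agents >= 1, dt > 0, induction_time >= 0,
            report_interval > 0, duration > 0)
  if (increment_ofd <= 0 || increment_nfd <= 0 ||
      increment_ofd > dt || increment_nfd > dt) {
    stop("increments must be positive and no larger than dt")
  }
  if (duration < induction_time + 1.46) {
    stop("duration must reach at least 1.46 u past induction_time")
  }
  structure(list(n_agents = as.integer(n_agents), dt = dt,
                 induction_time = induction_time,
                 increment_ofd = increment_ofd,
                 increment_nfd = increment_nfd,
                 report_interval = report_interval, duration = duration,
                 seed = as.integer(seed),
                 init_inheritance = init_inheritance),
            class = "sim_scenario")
}

#' Initialise a steady-state population of agents
#'
#' Ages are drawn by inverse-transform sampling of the ergodic age
#' distribution ([age_cdf()]), reproducing the bias towards early cell-cycle
#' stages that binary fission imposes on an exponentially growing culture.
#' Before induction every flagellum is fully labelled, so `old_label` is
#' FULL for all agents and `new_label` is FULL where a new flagellum exists
#' (progress above `b_2F`) and NONE below.
#'
#' @param scenario A [sim_scenario()]; its seed is applied here.
#' @param map A [cell_cycle_map()].
#' @return A `sim_population`: list of parallel vectors `progress`,
#'   `old_label`, `new_label`, `inheritance`.
#' @export
init_population <- function(scenario, map = cell_cycle_map()) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_agents
  progress <- progress_from_fraction(runif(n))
  new_label <- ifelse(progress > map$b_2F, LABEL_FULL, LABEL_NONE)
  inheritance <- switch(scenario$init_inheritance,
    random = sample(c(INH_OFD, INH_NFD), n, replace = TRUE),
    alternating = rep_len(c(INH_OFD, INH_NFD), n))
  structure(list(progress = progress,
                 old_label = rep(LABEL_FULL, n),
                 new_label = as.integer(new_label),
                 inheritance = as.integer(inheritance)),
            class = "sim_population")
}

#' Advance the population by one time step
#'
#' Each agent advances by the increment of its inheritance class. Agents
#' crossing the new-flagellum boundary `b_2F` acquire a new flagellum whose
#' label depends on when construction started relative to induction: FULL
#' before induction, UNLABELLED after. At the single step containing the
#' induction time, every cell already past `b_2F` (a two-flagella cell with
#' a part-built new flagellum) has its new flagellum re-flagged PARTIAL.
#' Agents reaching progress 1 divide via [divide_agents()].
#'
#' @param pop A `sim_population`.
#' @param scenario A [sim_scenario()].
#' @param map A [cell_cycle_map()].
#' @param t_now Global time (u) before the step.
#' @return Updated `sim_population`.
#' @export
step_population <- function(pop, scenario, map = cell_cycle_map(), t_now) {
  stopifnot(inherits(pop, "sim_population"), inherits(scenario, "sim_scenario"))
  t_next <- t_now + scenario$dt
  inc <- ifelse(pop$inheritance == INH_NFD,
                scenario$increment_nfd, scenario$increment_ofd)
  old_progress <- pop$progress
  pop$progress <- old_progress + inc

  induced_before <- t_now >= scenario$induction_time
  induction_step <- !induced_before & t_next >= scenario$induction_time

  crossed <- old_progress <= map$b_2F & pop$progress > map$b_2F
  if (any(crossed)) {
    pop$new_label[crossed] <-
      if (induced_before) LABEL_UNLABELLED else LABEL_FULL
  }
  if (induction_step) {
    two_f <- pop$progress > map$b_2F
    pop$new_label[two_f] <- LABEL_PARTIAL
  }

  dividing <- pop$progress >= 1
  if (any(dividing)) pop <- divide_agents(pop, which(dividing))
  pop
}

#' Divide agents that completed the cycle
#'
#' The parent continues as the old-flagellum daughter: progress reset to
#' exactly 0 (overshoot discarded), old label retained, new-flagellum slot
#' reset to NONE. A new agent is appended as the new-flagellum daughter,
#' whose (now old) flagellum inherits the label of the parent's new
#' flagellum.
#'
#' @param pop A `sim_population`.
#' @param idx Integer indices of agents with progress at or past 1.
#' @return Updated `sim_population` with `length(idx)` new agents appended.
#' @export
divide_agents <- function(pop, idx) {
  if (length(idx) == 0L) return(pop)
  if (any(pop$progress[idx] < 1)) stop("divide called on agents below 1 u")
  if (any(pop$new_label[idx] == LABEL_NONE)) {
    stop("dividing agent has no new flagellum")
  }
  child_old <- pop$new_label[idx]
  pop$progress[idx] <- 0
  pop$new_label[idx] <- LABEL_NONE
  pop$inheritance[idx] <- INH_OFD
  n_child <- length(idx)
  pop$progress <- c(pop$progress, rep(0, n_child))
  pop$old_label <- c(pop$old_label, child_old)
  pop$new_label <- c(pop$new_label, rep(LABEL_NONE, n_child))
  pop$inheritance <- c(pop$inheritance, rep(INH_NFD, n_child))
  pop
}

tally_population <- function(pop, map, t_now) {
  stage <- classify_stage(pmin(pop$progress, 1 - 1e-12), map)
  affected <- pop$old_label != LABEL_FULL
  tab <- table(stage = stage,
               old_label_class = factor(ifelse(affected, "affected", "full"),
                                        levels = c("full", "affected")))
  df <- as.data.frame(tab, responseName = "count")
  df$time_u <- t_now
  df[, c("time_u", "stage", "old_label_class", "count")]
}

#' Run the label-inheritance simulation
#'
#' Steps an initial steady-state population from time 0 to
#' `scenario$duration`, reporting the population composition every
#' `report_interval`: counts of cells cross-classified by morphological
#' category (`1F1K1N`, `2F1K1N`, `2F2K1N`, `2F2K2N`) and by old-flagellum
#' label class (`full` = unaffected by RNAi, `affected` = partially
#' labelled or unlabelled). Under equal increments the population
#' approximately doubles per cycle unit.
#'
#' @param scenario A [sim_scenario()].
#' @param map A [cell_cycle_map()].
#' @return A `sim_report`: data frame with columns `time_u`, `stage`,
#'   `old_label_class`, `count`, one row per combination per report time,
#'   with the scenario attached as attribute `"scenario"`.
#' @examples
#' rep <- run_labelling_sim(sim_scenario(n_agents = 500, seed = 2))
#' plateau_fraction(rep)
#' @export
run_labelling_sim <- function(scenario = sim_scenario(),
                              map = cell_cycle_map()) {
  pop <- init_population(scenario, map)
  n_steps <- round(scenario$duration / scenario$dt)
  report_every <- max(1L, round(scenario$report_interval / scenario$dt))
  out <- vector("list", floor(n_steps / report_every) + 1L)
  out[[1]] <- tally_population(pop, map, 0)
  k_out <- 1L
  for (k in seq_len(n_steps)) {
    t_now <- (k - 1L) * scenario$dt
    pop <- step_population(pop, scenario, map, t_now)
    if (k %% report_every == 0L) {
      k_out <- k_out + 1L
      out[[k_out]] <- tally_population(pop, map, k * scenario$dt)
    }
  }
  report <- do.call(rbind, out[seq_len(k_out)])
  rownames(report) <- NULL
  attr(report, "scenario") <- scenario
  class(report) <- c("sim_report", "data.frame")
  report
}

#' Plateau fraction of fully-labelled 1K1N cells
#'
#' The readout that compares the cycle durations of the two daughter
#' classes: among 1K1N cells (the `1F1K1N` and `2F1K1N` categories pooled,
#' mirroring classification of experimental cells by kinetoplast/nucleus
#' counts only), the fraction whose old flagellum is still fully labelled,
#' averaged over all report times within a window. The window is expressed
#' on the simulation clock, whose origin is the moment RNAi induction
#' starts (doxycycline addition); the scenario's `induction_time` is the
#' delay before induction takes effect. The default window 1.24-1.46 u is
#' the 11-13 h span where the measured proportion plateaus. With equal
#' division rates the model holds exactly 50% while every affected 1K1N
#' cell still has a live fully-labelled sibling born at the same division
#' (up to `induction_time + 1` u), then eases off as affected-lineage
#' divisions begin.
#'
#' @param report A `sim_report` from [run_labelling_sim()].
#' @param window Numeric length-2 window in cycle units.
#' @param clock `"simulation"` (default): window measured from time 0;
#'   `"post_induction"`: window measured from the scenario's
#'   `induction_time`.
#' @param map A [cell_cycle_map()] (unused by the tally, kept for interface
#'   symmetry).
#' @return Mean fraction (0-1) of `full` among 1K1N cells over the window.
#' @export
plateau_fraction <- function(report, window = c(1.24, 1.46),
                             clock = c("simulation", "post_induction"),
                             map = cell_cycle_map()) {
  stopifnot(inherits(report, "sim_report"), length(window) == 2L,
            window[2] > window[1])
  clock <- match.arg(clock)
  scenario <- attr(report, "scenario")
  offset <- if (clock == "post_induction") scenario$induction_time else 0
  t_lo <- offset + window[1]
  t_hi <- offset + window[2]
  eps <- 1e-9
  times <- sort(unique(report$time_u))
  in_win <- times[times >= t_lo - eps & times <= t_hi + eps]
  if (length(in_win) == 0L) stop("no report times fall in the plateau window")
  sel <- report[report$time_u %in% in_win &
                  report$stage %in% c("1F1K1N", "2F1K1N"), ]
  per_time <- vapply(split(sel, sel$time_u), function(d) {
    full <- sum(d$count[d$old_label_class == "full"])
    full / sum(d$count)
  }, numeric(1))
  mean(per_time)
}

#' Total population size at each report time
#'
#' @param report A `sim_report`.
#' @return Named numeric vector of population sizes by report time.
#' @export
population_sizes <- function(report) {
  stopifnot(inherits(report, "sim_report"))
  vapply(split(report$count, report$time_u), sum, numeric(1))
}
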