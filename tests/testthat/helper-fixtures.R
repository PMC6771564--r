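# Shared fixtures and the brute-force population oracle.

# Build a bare agent population for step-level tests.
make_population <- function(progress, old_label = NULL, new_label = NULL,
                            inheritance = NULL, map = cell_cycle_map()) {
  n <- length(progress)
  FULL <- trypcycle:::LABEL_FULL
  NONE <- trypcycle:::LABEL_NONE
  if (is.null(old_label)) old_label <- rep(FULL, n)
  if (is.null(new_label)) {
    new_label <- ifelse(progress > map$b_2F, FULL, NONE)
  }
  if (is.null(inheritance)) inheritance <- rep(trypcycle:::INH_OFD, n)
  structure(list(progress = progress, old_label = as.integer(old_label),
                 new_label = as.integer(new_label),
                 inheritance = as.integer(inheritance)),
            class = "sim_population")
}

# Forward population simulation marking one daughter per division: the
# dynamics-based oracle against which the closed-form snapshot estimator
# is checked. Ages advance deterministically; at each division the
# continuing cell is unmarked and the newborn sibling carries the marker,
# which is scored as visible while its age is below w.
simulate_marked_population <- function(w, n0 = 5000, duration = 1.5,
                                       dt = w / 20, seed = 1) {
  # dt must divide w: birth cohorts sit on the age grid, so counting
  # age < w otherwise widens the window to ceiling(w / dt) * dt
  set.seed(seed)
  age <- progress_from_fraction(runif(n0))
  marked <- rep(FALSE, n0)
  for (k in seq_len(round(duration / dt))) {
    age <- age + dt
    div <- which(age >= 1)
    if (length(div)) {
      age[div] <- 0
      marked[div] <- FALSE
      age <- c(age, rep(0, length(div)))
      marked <- c(marked, rep(TRUE, length(div)))
    }
  }
  list(n_marked = sum(marked & age < w), N_total = length(age))
}

fraction_full_1k1n <- function(report, time_u) {
  d <- report[abs(report$time_u - time_u) < 1e-9 &
                report$stage %in% c("1F1K1N", "2F1K1N"), ]
  sum(d$count[d$old_label_class == "full"]) / sum(d$count)
}
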