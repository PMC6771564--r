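test_that("snapshot generation is seeded, exclusive and window-faithful", {
  sp <- snapshot_spec(n_cells = 5000L, seed = 8)
  snap <- generate_snapshot(sp)
  expect_equal(nrow(snap), 5000L)
  expect_identical(snap, generate_snapshot(sp))
  # the two remnant markers never co-occur
  expect_equal(sum(snap$tip_marker & snap$mid_marker), 0)
  # markers only on 1F1K1N cells
  marked <- snap$tip_marker == 1 | snap$mid_marker == 1
  expect_true(all(snap$n_flagella[marked] == 1))
  # a zero window leaves no marked cells
  none <- generate_snapshot(snapshot_spec(n_cells = 2000L, w_tip = 0,
                                          w_mid = 0, seed = 2))
  expect_equal(sum(none$tip_marker) + sum(none$mid_marker), 0)
  expect_error(snapshot_spec(w_tip = 0.7), "1F1K1N span")
  # free flagellum never exceeds the flagellum
  expect_true(all(snap$free_flagellum_um <= snap$flagellum_um + 1e-9))
})

test_that("marked fractions match the ergodic expectation", {
  sp <- snapshot_spec(n_cells = 100000L, seed = 42)
  snap <- generate_snapshot(sp)
  for (case in list(list(frac = mean(snap$tip_marker), w = sp$w_tip),
                    list(frac = mean(snap$mid_marker), w = sp$w_mid))) {
    expected <- age_cdf(case$w) / 2
    se <- sqrt(expected * (1 - expected) / nrow(snap))
    expect_lt(abs(case$frac - expected), 3 * se)
  }
  # age structure of the snapshot matches the ergodic CDF
  ks <- suppressWarnings(stats::ks.test(attr(snap, "progress"),
                                        function(q) age_cdf(q)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the estimator recovers the generating windows from a snapshot", {
  sp <- snapshot_spec(n_cells = 100000L, seed = 9)
  snap <- generate_snapshot(sp)
  rw <- recover_windows(snap, sp$map)
  for (case in list(list(est = rw$tip, w = sp$w_tip),
                    list(est = rw$mid, w = sp$w_mid))) {
    # 3-binomial-SE band on the marked fraction, mapped through the inverse
    F_hat <- case$est$F_eff / 2
    se <- 3 * sqrt(F_hat * (1 - F_hat) / nrow(snap))
    lo <- progress_from_fraction(2 * max(F_hat - se, 0))
    hi <- progress_from_fraction(2 * min(F_hat + se, 1))
    expect_gte(case$w, lo)
    expect_lte(case$w, hi)
  }
  tiny <- generate_snapshot(snapshot_spec(n_cells = 200L, w_tip = 0,
                                          w_mid = 0, seed = 3))
  warns <- capture_warnings(rw0 <- recover_windows(tiny))
  expect_length(warns, 2L)              # one zero-window warning per marker
  expect_match(warns, "zero window", all = TRUE)
  expect_equal(rw0$w_tip_est, 0)
  expect_equal(rw0$w_mid_est, 0)
})

test_that("generated cohorts reproduce the published morphometric ordering", {
  snap <- generate_snapshot(snapshot_spec(n_cells = 8000L, seed = 14))
  cls <- classify_cohort(snap)
  # trim to 50 cells per cohort, the cohort size used for the measurements
  keep <- unlist(lapply(c("NFD", "OFD", "NO_FCR"), function(co) {
    head(which(cls == co), 50)
  }))
  expect_length(keep, 150L)
  cs <- cohort_summary(snap[keep, ])
  get <- function(p, co) {
    r <- cs$summaries[cs$summaries$parameter == p & cs$summaries$cohort == co, ]
    r$mean
  }
  ptest <- function(p) {
    r <- cs$tests[cs$tests$parameter == p & cs$tests$cohort_a == "NFD" &
                    cs$tests$cohort_b == "OFD", ]
    r$significant
  }
  for (p in c("flagellum_um", "cell_body_um", "faz_um", "kn_dist_um")) {
    expect_lt(get(p, "NFD"), get(p, "OFD"))
    expect_true(ptest(p))
  }
  expect_gt(get("free_flagellum_um", "NFD"), get("free_flagellum_um", "OFD"))
  expect_true(ptest("free_flagellum_um"))
  # anterior angle separates the tapered from the non-tapered daughters
  expect_gt(get("anterior_angle_deg", "NFD"), get("anterior_angle_deg", "OFD"))
  expect_true(ptest("anterior_angle_deg"))
})

test_that("timecourse subsampling emulates counting 500 cells", {
  sc <- sim_scenario(n_agents = 2000L, seed = 6)
  tc <- generate_timecourse(sc, sample_size = 500L, timepoints = c(0, 1.25),
                            seed = 4)
  for (tp in c(0, 1.25)) {
    expect_equal(sum(tc$count[tc$time_u == tp]), 500L)
  }
  expect_equal(fraction_full_1k1n(tc, 0), 1.0)
  # the sampled plateau fraction is binomial noise around the population
  # value of 1/2; average a few independent counts of 500 cells
  f <- vapply(1:5, function(s) {
    fraction_full_1k1n(generate_timecourse(sc, sample_size = 500L,
                                           timepoints = 1.25, seed = s),
                       1.25)
  }, numeric(1))
  expect_lt(abs(mean(f) - 0.5), 3 * sqrt(0.25 / (0.8 * 500)) / sqrt(5))
  # sampling the whole population returns the exact tallies
  full_rep <- run_labelling_sim(sc)
  n0 <- sum(full_rep$count[full_rep$time_u == 0])
  tc_all <- generate_timecourse(sc, sample_size = n0, timepoints = 0, seed = 1)
  expect_equal(tc_all$count, full_rep$count[full_rep$time_u == 0])
  expect_error(generate_timecourse(sc, sample_size = 10 * n0, timepoints = 0),
               "exceeds population")
})

test_that("paired tube profiles reproduce the published caliber contrast", {
  # anterior caliber 2 um from the tip: non-tapered daughter ~908 nm,
  # tapered daughter ~403 nm
  nfd <- generate_tapered_tube(linear_taper(350, 766, 8000), 8000,
                               n_axial = 300, n_circ = 96)
  ofd <- generate_tapered_tube(linear_taper(100, 506, 8000), 8000,
                               n_axial = 300, n_circ = 96)
  cal_n <- anterior_caliber(nfd$mesh, nfd$path)
  cal_o <- anterior_caliber(ofd$mesh, ofd$path)
  expect_equal(cal_n / cal_o, 908 / 403, tolerance = 0.05)
  z_n <- nfd$z_of_arclength(2000)
  expect_equal(cal_n, 2 * nfd$radius_fun(z_n), tolerance = 0.02)
})
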