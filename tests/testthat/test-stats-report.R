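test_that("trajectory features match closed-form OLS", {
  tc <- round(exp(seq(log(30), log(780), length.out = 20)))
  q_lin <- 0.1 + 0.02 * log(tc)
  f <- trajectory_features(q_lin, tc)
  expect_equal(f$slope, 0.02, tolerance = 1e-12)
  expect_equal(f$early, mean(q_lin[1:3]))
  # constant series
  f0 <- trajectory_features(rep(0.3, 20), tc)
  expect_equal(f0$slope, 0)
  expect_equal(f0$early, 0.3)
  # random series against an independent normal-equations solve
  set.seed(701)
  q <- rnorm(20)
  D <- cbind(1, log(tc))
  beta <- solve(t(D) %*% D, t(D) %*% q)
  expect_equal(trajectory_features(q, tc)$slope, beta[2], tolerance = 1e-10)
  expect_error(trajectory_features(c(q[1:5], NA, q[7:20]), tc),
               "missing windows: 6")
  expect_error(trajectory_features(q[1:3], tc[1:3]), "at least 4")
})

test_that("t statistics agree with textbook closed forms on 3-point inputs", {
  x <- c(1, 2, 4)
  y <- c(2, 2, 5)
  s <- data.frame(q_slope = x, early_q = x, learning_rate = y,
                  habit_strength = y, v_compatible = x, v_incompatible = y)
  s5 <- rbind(s, s[1, ], s[2, ]) # >= 5 subjects
  rep_ <- cohort_statistics(s5)
  xs <- s5$q_slope
  expect_equal(rep_$q_slope_t$t,
               mean(xs) / (sd(xs) / sqrt(length(xs))), tolerance = 1e-12)
  d <- s5$v_compatible - s5$v_incompatible
  expect_equal(rep_$drift_paired_t$t,
               mean(d) / (sd(d) / sqrt(length(d))), tolerance = 1e-12)
  # Welch t between two cohorts
  o <- data.frame(q_slope = c(0, 1, 2, 1, 0), learning_rate = c(1, 2, 3, 2, 1))
  rep2 <- cohort_statistics(s5, other = o)
  a <- s5$q_slope; b <- o$q_slope
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(rep2$welch_between_cohorts$q_slope$t, tw, tolerance = 1e-12)
})

test_that("Pearson entries are duplication-invariant and flag zero variance", {
  set.seed(702)
  s <- data.frame(q_slope = rnorm(10), early_q = rnorm(10),
                  learning_rate = rnorm(10), habit_strength = rnorm(10))
  r1 <- cohort_statistics(s)
  r2 <- cohort_statistics(rbind(s, s))
  expect_equal(r1$r_qslope_learning$r, r2$r_qslope_learning$r,
               tolerance = 1e-12)
  s0 <- s
  s0$habit_strength <- 1
  r3 <- cohort_statistics(s0)
  expect_true(r3$r_qslope_habit$flagged)
  expect_false(r3$r_qslope_learning$flagged)
  expect_error(cohort_statistics(s[1:4, ]), ">= 5")
})

test_that("the median split balances group sizes for odd cohorts", {
  set.seed(703)
  s <- data.frame(q_slope = rnorm(11), early_q = rnorm(11),
                  learning_rate = c(rnorm(9), 1.5, 1.5),
                  habit_strength = rnorm(11))
  r <- cohort_statistics(s)
  expect_lte(abs(r$median_split$n_fast - r$median_split$n_slow), 1)
  expect_gt(r$median_split$fast_mean_learning_rate,
            r$median_split$slow_mean_learning_rate)
})

test_that("cartography profiles apply Bonferroni FWE across networks and metrics", {
  set.seed(704)
  pc <- matrix(rnorm(60, mean = 0.02, sd = 0.01), 15, 4,
               dimnames = list(NULL, paste0("N", 1:4)))
  mdz <- matrix(rnorm(60, mean = -0.3, sd = 0.1), 15, 4,
                dimnames = list(NULL, paste0("N", 1:4)))
  prof <- cartography_profile(pc, mdz)
  expect_equal(prof$p_pc_fwe, pmin(1, 8 * prof$p_pc), tolerance = 1e-12)
  expect_true(all(prof$p_pc_fwe >= prof$p_pc))
  expect_true(all(prof$t_mdz < 0))
  # all-zero slopes: t = 0, p = 1 by convention
  z <- matrix(0, 15, 4)
  prof0 <- cartography_profile(z, z)
  expect_equal(prof0$t_pc, rep(0, 4))
  expect_equal(prof0$p_pc, rep(1, 4))
})

test_that("the pipeline is deterministic and honours skip flags", {
  cfg <- cohort_config(n_subjects = 5, n_nodes = 16, n_networks = 4,
                       scans_per_subject = 120, n_stimuli = 2,
                       phase3_trials_per_condition = 25, n_windows = 6,
                       behavior_bin_width = 14, consensus_runs = 3,
                       seed = 1234)
  r1 <- suppressMessages(run_pipeline(cfg, cartography = FALSE))
  r2 <- suppressMessages(run_pipeline(cfg, cartography = FALSE))
  expect_identical(r1$q_table, r2$q_table)
  expect_identical(r1$summaries, r2$summaries)
  expect_identical(r1$prevalence$prevalence, r2$prevalence$prevalence)
  # written reports are byte-identical apart from the timestamped log
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_pipeline_report(r1, d1)
  write_pipeline_report(r2, d2)
  for (f in c("subject_summaries.csv", "q_by_window.csv",
              "state_prevalence.csv", "stats_report.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # skipping behavior drops the brain-behaviour battery but keeps the rest
  r3 <- suppressMessages(run_pipeline(cfg, skip_behavior = TRUE,
                                      cartography = FALSE))
  expect_null(r3$stats)
  expect_false("learning_rate" %in% names(r3$summaries))
  expect_identical(dim(r3$q_table), dim(r1$q_table))
})
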