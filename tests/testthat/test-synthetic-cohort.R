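test_that("invalid configurations are rejected", {
  expect_error(cohort_config(coupling_rho = 1), "rho")
  expect_error(cohort_config(within_r_segregated = 0.2,
                             within_r_integrated = 0.3), "higher within")
  expect_error(cohort_config(between_r_segregated = 0.5), "lower between")
  expect_error(cohort_config(n_nodes = 0), "positive")
  expect_error(cohort_config(noise_sd = 0), "noise_sd")
})

test_that("subject parameters realise the configured coupling", {
  set.seed(601)
  g0 <- draw_subject_parameters(cohort_config(n_subjects = 1000,
                                              coupling_rho = 0))
  expect_lt(abs(cor(g0$transition_rate, g0$learning_exponent)), 0.1)
  set.seed(602)
  g5 <- draw_subject_parameters(cohort_config(n_subjects = 1000,
                                              coupling_rho = -0.5))
  r <- cor(g5$transition_rate, g5$learning_exponent)
  expect_gte(r, -0.6)
  expect_lte(r, -0.4)
  # habit stays uncoupled by default
  expect_lt(abs(cor(g5$habit_effect, g5$transition_rate)), 0.1)
  # empty cohort: empty table, no error
  g_empty <- draw_subject_parameters(cohort_config(n_subjects = 0))
  expect_equal(nrow(g_empty), 0)
})

test_that("state covariances are PSD, block-structured, and ordered by segregation", {
  cfg <- cohort_config()
  atlas <- default_atlas(cfg)
  covs <- build_state_covariances(atlas, cfg)
  for (S in covs) {
    expect_equal(diag(S), rep(1, cfg$n_nodes), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  expect_gt(system_segregation(covs$segregated, atlas),
            system_segregation(covs$integrated, atlas))
})

test_that("the prevalence logistic honours its limits", {
  # flat logistic at zero rate with a fixed midpoint
  expect_equal(segregated_prevalence(seq(0, 1, 0.1), 0, midpoint = 0.5),
               rep(0.5, 11))
  # step-function limit: huge rate with midpoint 0.5 splits the session
  u <- c(0.1, 0.3, 0.49, 0.51, 0.7, 0.9)
  p <- segregated_prevalence(u, 1e6, midpoint = 0.5)
  expect_equal(p, c(0, 0, 0, 1, 1, 1), tolerance = 1e-6)
  # default midpoint scales inversely with rate: same start prevalence
  expect_equal(segregated_prevalence(0, 8, midpoint_scale = 1.5),
               segregated_prevalence(0, 30, midpoint_scale = 1.5))
})

test_that("a simulated subject switches from integrated to segregated states", {
  set.seed(603)
  cfg <- cohort_config(n_subjects = 1, n_nodes = 20, n_networks = 4,
                       scans_per_subject = 300)
  atlas <- default_atlas(cfg)
  covs <- build_state_covariances(atlas, cfg)
  gt <- draw_subject_parameters(cfg)
  # step-function limit with a fixed mid-session midpoint
  ts_step <- simulate_subject(transform(gt, transition_rate = 1e6),
                              covs, cfg, atlas, midpoint = 0.5)
  segs <- ts_step$segments
  expect_true(all(segs$state[segs$u < 0.5] == 1L))
  expect_true(all(segs$state[segs$u > 0.5] == 2L))
  # default midpoint: segregated occupancy rises over windows
  ts <- simulate_subject(gt, covs, cfg, atlas)
  plan <- plan_windows(300, 10, "non_overlapping")
  occ <- sapply(seq_len(10), function(w) {
    mean(ts$state_scan[plan$windows$start[w]:plan$windows$end[w]] == 2L)
  })
  expect_gt(cor(seq_along(occ), occ, method = "spearman"), 0)
  expect_equal(ncol(ts$data), 300)
  expect_equal(length(ts$state_scan), 300)
})

test_that("behavioral trials carry both phases with valid fields", {
  set.seed(604)
  cfg <- cohort_config(n_subjects = 2, phase3_trials_per_condition = 25)
  gt <- draw_subject_parameters(cfg)
  tr <- simulate_behavior_cohort(gt, cfg)
  expect_setequal(unique(tr$phase), c(2, 3))
  expect_true(all(tr$rt_seconds > 0))
  expect_true(all(tr$accuracy %in% 0:1))
  ph2 <- tr[tr$phase == 2 & tr$subject_id == gt$subject_id[1], ]
  expect_setequal(unique(ph2$condition), c("approach", "avoidance"))
  expect_lte(max(ph2$repetition), cfg$n_repetitions)
  ph3 <- tr[tr$phase == 3, ]
  expect_setequal(unique(ph3$condition), c("compatible", "incompatible"))
  bad <- gt
  bad$a <- -1
  expect_error(simulate_behavior_cohort(bad, cfg), "non-positive")
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 2, n_nodes = 16, n_networks = 4,
                       scans_per_subject = 120, n_stimuli = 2,
                       phase3_trials_per_condition = 25, seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$timeseries[[1]]$data, c2$timeseries[[1]]$data)
  expect_identical(c1$trials, c2$trials)
})

test_that("cohort files round-trip through the delimited formats", {
  set.seed(605)
  cfg <- cohort_config(n_subjects = 1, n_nodes = 12, n_networks = 3,
                       scans_per_subject = 80, n_stimuli = 2,
                       phase3_trials_per_condition = 25, seed = 7)
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(cfg, out_dir = dir)
  atlas2 <- read_atlas(file.path(dir, "atlas.tsv"))
  expect_equal(atlas2$network_of_node, cohort$atlas$network_of_node)
  ts2 <- read_timeseries(file.path(dir, "timeseries_sub001.tsv"))
  expect_equal(unname(ts2$data), unname(cohort$timeseries[[1]]$data),
               tolerance = 1e-12)
  tr2 <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(nrow(tr2), nrow(cohort$trials))
  expect_equal(tr2$rt_seconds, cohort$trials$rt_seconds, tolerance = 1e-12)
})
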