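test_that("DDM simulation respects its limiting regimes", {
  set.seed(501)
  # drift-dominated limit: near-certain fast hits just above t_er
  fast <- simulate_ddm_trials(50, 1.2, 0.3, n_trials = 300)
  expect_gte(mean(fast$accuracy), 0.99)
  expect_lt(mean(fast$rt) - 0.3, 0.05)
  # symmetric random walk: chance accuracy
  null <- simulate_ddm_trials(0, 1.2, 0.3, n_trials = 4000)
  expect_lt(abs(mean(null$accuracy) - 0.5), 0.03)
  expect_error(simulate_ddm_trials(1, -1, 0.3, n_trials = 10), "a > 0")
})

test_that("simulated hit probability matches the first-passage closed form", {
  set.seed(502)
  v <- 1.5; a <- 1.2
  sim <- simulate_ddm_trials(v, a, 0.3, n_trials = 10000)
  analytic <- 1 / (1 + exp(-v * a)) # boundaries {0, a}, start a/2, s = 1
  expect_lt(abs(mean(sim$accuracy) - analytic), 0.01)
})

test_that("EZ moment inversion recovers known DDM parameters", {
  set.seed(503)
  sim <- simulate_ddm_trials(1.5, 1.2, 0.3, n_trials = 2000)
  fit <- ez_fit(sim)
  expect_lt(abs(fit$v - 1.5) / 1.5, 0.05)
  expect_lt(abs(fit$a - 1.2) / 1.2, 0.05)
  expect_lt(abs(fit$t_er - 0.3) / 0.3, 0.10)
  # drift ordering is preserved
  lo <- ez_fit(simulate_ddm_trials(0.8, 1.2, 0.3, n_trials = 1500))
  hi <- ez_fit(simulate_ddm_trials(2.0, 1.2, 0.3, n_trials = 1500))
  expect_lt(lo$v, hi$v)
})

test_that("EZ estimator bias in v shrinks with sample size", {
  set.seed(504)
  bias <- sapply(c(200, 2000, 20000), function(n) {
    abs(ez_fit(simulate_ddm_trials(1.5, 1.2, 0.3, n_trials = n))$v - 1.5)
  })
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1])
})

test_that("EZ handles edge-case accuracies", {
  set.seed(505)
  # perfect accuracy uses the (x + 0.5)/(n + 1) correction and stays finite
  perfect <- data.frame(accuracy = rep(1, 100),
                        rt = 0.4 + abs(rnorm(100, 0, 0.08)))
  fit <- ez_fit(perfect)
  expect_true(is.finite(fit$v))
  expect_gt(fit$v, 0)
  # all errors flip the drift sign by accuracy-coding symmetry
  wrong <- data.frame(accuracy = rep(0, 100),
                      rt = 0.4 + abs(rnorm(100, 0, 0.08)))
  expect_lt(ez_fit(wrong)$v, 0)
  expect_error(ez_fit(perfect[1:5, ]), "fewer than")
})

test_that("drift curves track a rising generator and stay flat without learning", {
  set.seed(506)
  g_rise <- data.frame(subject_id = "s1", transition_rate = 16,
                       learning_exponent = 0.45, habit_effect = 0,
                       a = 1.2, t_er = 0.3, z = 0.5)
  cfg <- cohort_config(n_subjects = 1, phase3_trials_per_condition = 20)
  # average fitted curves over replicate sessions to beat per-bin noise,
  # then compare against the generating drift at the bin centres
  curves <- replicate(20, {
    tr <- simulate_behavior_cohort(g_rise, cfg)
    ph2 <- tr[tr$phase == 2, ]
    drift_curve(data.frame(repetition = ph2$repetition,
                           accuracy = ph2$accuracy,
                           rt = ph2$rt_seconds))$v
  })
  mean_curve <- rowMeans(curves)
  k <- seq(4, 95, by = 7)
  v_true <- 2.5 * pmin(1, 0.35 * log(k + 1)^0.45)
  expect_gt(cor(mean_curve, v_true), 0.9)
  expect_gt(mean(utils::tail(mean_curve, 5)), mean(utils::head(mean_curve, 5)))
  curve <- data.frame(k = k, v = mean_curve)
  # nearly flat generator: fitted learning rate close to zero
  g_flat <- g_rise
  g_flat$learning_exponent <- 0.05
  tr2 <- simulate_behavior_cohort(g_flat, cfg)
  ph2f <- tr2[tr2$phase == 2, ]
  cf <- drift_curve(data.frame(repetition = ph2f$repetition,
                               accuracy = ph2f$accuracy,
                               rt = ph2f$rt_seconds))
  expect_lt(abs(fit_learning_rate(cf)$learning_rate), 0.3)
  # degenerate binning refuses the power fit
  c1 <- drift_curve(data.frame(repetition = ph2f$repetition,
                               accuracy = ph2f$accuracy,
                               rt = ph2f$rt_seconds), bin_width = 98)
  expect_equal(nrow(c1), 1)
  expect_error(fit_learning_rate(c1), ">= 3")
})

test_that("the power fit returns an exact exponent on noiseless curves", {
  k <- seq(4, 95, by = 7)
  for (b in c(0.1, 0.3, 0.55)) {
    curve <- data.frame(k = k, v = 1.4 * log(k + 1)^b)
    fit <- fit_learning_rate(curve)
    expect_equal(fit$learning_rate, -b, tolerance = 1e-6)
    expect_equal(fit$coefficient, 1.4, tolerance = 1e-4)
  }
})

test_that("LAR resists a gross outlier better than least squares", {
  set.seed(507)
  k <- seq(4, 95, by = 7)
  b <- 0.3
  wins <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    v <- 1.4 * log(k + 1)^b
    v[sample(length(v), 1)] <- v[1] * runif(1, 3, 6) # one wild bin
    curve <- data.frame(k = k, v = v)
    e_lar <- abs(fit_learning_rate(curve, "LAR")$exponent - b)
    e_ls <- abs(fit_learning_rate(curve, "LS")$exponent - b)
    if (e_lar < e_ls) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.9)
})

test_that("steeper generating exponents yield larger fitted exponents", {
  set.seed(508)
  cfg <- cohort_config(n_subjects = 1, phase3_trials_per_condition = 20)
  grid <- seq(0.1, 0.6, by = 0.1)
  fitted <- sapply(grid, function(b) {
    mean(replicate(4, {
      g <- data.frame(subject_id = "s", transition_rate = 16,
                      learning_exponent = b, habit_effect = 0,
                      a = 1.2, t_er = 0.3, z = 0.5)
      tr <- simulate_behavior_cohort(g, cfg)
      ph2 <- tr[tr$phase == 2, ]
      cv <- drift_curve(data.frame(repetition = ph2$repetition,
                                   accuracy = ph2$accuracy,
                                   rt = ph2$rt_seconds))
      fit_learning_rate(cv)$exponent
    }))
  })
  expect_gt(cor(grid, fitted, method = "spearman"), 0.9)
})

test_that("habit strength recovers the generated drift difference and is antisymmetric", {
  set.seed(509)
  make_cond <- function(v, cond, n) {
    s <- simulate_ddm_trials(v, 1.2, 0.3, n_trials = n)
    data.frame(condition = cond, accuracy = s$accuracy, rt = s$rt)
  }
  hs <- replicate(12, {
    tr <- rbind(make_cond(1.48, "compatible", 2000),
                make_cond(1.35, "incompatible", 2000))
    habit_strength(tr)$habit_strength
  })
  expect_lt(abs(mean(hs) - 0.13), 0.05)
  tr <- rbind(make_cond(1.48, "compatible", 2000),
              make_cond(1.35, "incompatible", 2000))
  h <- habit_strength(tr)
  swapped <- tr
  swapped$condition <- ifelse(tr$condition == "compatible",
                              "incompatible", "compatible")
  expect_equal(habit_strength(swapped)$habit_strength, -h$habit_strength)
  # null case: identical conditions give a near-zero cohort mean
  set.seed(510)
  diffs <- replicate(12, {
    tr0 <- rbind(make_cond(1.4, "compatible", 400),
                 make_cond(1.4, "incompatible", 400))
    habit_strength(tr0)$habit_strength
  })
  expect_lt(abs(mean(diffs)), 0.05)
  expect_error(habit_strength(tr[tr$condition == "compatible", ]), "required")
})

test_that("cohort outlier flagging applies the 3-SD rule", {
  set.seed(511)
  vals <- rnorm(30, 0.13, 0.1)
  vals[7] <- mean(vals) + 4.5 * sd(vals)
  fl <- flag_outliers(vals)
  expect_true(fl[7])
  expect_lte(sum(fl), 2)
})
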