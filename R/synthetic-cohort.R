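#' Synthetic cohort configuration
#'
#' Defines the study conditions for the synthetic cohort: a two-state
#' (integrated vs segregated) block-covariance model of regional time
#' series whose segregated-state prevalence rises along a subject-specific
#' logistic, coupled to drift-diffusion behaviour whose drift rate grows as
#' a one-term power law in log repetition.
#'
#' The default within/between correlations place the two states' within-
#' network connectivity 0.5 apart on the Fisher-z scale (`tanh(0.3)` vs
#' `tanh(0.8)`), with stronger between-network anticorrelation in the
#' segregated state, so the segregated state scores higher system
#' segregation by construction.
#'
#' @param n_subjects cohort size (default 40).
#' @param n_nodes number of regions (default 60; formulas are
#'   size-agnostic up to the 227-node, 10-network scale).
#' @param n_networks number of a-priori networks (default 4).
#' @param scans_per_subject scans per subject (default 700).
#' @param n_stimuli phase-2 stimuli (default 8).
#' @param n_repetitions repetitions per stimulus (default 98).
#' @param phase3_trials_per_condition phase-3 trials per compatibility
#'   condition (default 96).
#' @param within_r_integrated,between_r_integrated within-/between-network
#'   correlation of the integrated state.
#' @param within_r_segregated,between_r_segregated same for the segregated
#'   state; must be more segregated (higher within, lower between).
#' @param coupling_rho correlation between transition rate and learning
#'   exponent (default -0.5: faster network transition goes with a smaller
#'   exponent, i.e. a higher learning rate).
#' @param habit_rho correlation of habit strength with both (default 0).
#' @param noise_sd isotropic measurement noise s.d. (default 0.2).
#' @param rate_mean,rate_sd logistic transition-rate distribution
#'   (default 16, 4.5).
#' @param exponent_mean,exponent_sd power-law exponent distribution
#'   (default 0.38, 0.16, the scale reported for slow-learning cohorts).
#' @param habit_mean,habit_sd true compatible-incompatible drift difference
#'   distribution (default 0.13, 0.10).
#' @param v_max,drift_alpha drift power-law cap and coefficient
#'   (default 2.5, 0.35; the cap never binds for exponents below ~0.7).
#' @param a_mean,a_sd,ter_mean,ter_sd per-subject DDM baseline
#'   distributions (boundary and non-decision time).
#' @param phase3_v baseline phase-3 drift (default 1.35).
#' @param segment_length_scans length of a constant-state segment
#'   (default 2 scans, so each sliding window averages many
#'   independent state draws).
#' @param midpoint_scale constant `c0` of the default subject-specific
#'   logistic midpoint `c0 / transition_rate` (see vignette).
#' @param behavior_bin_width repetitions pooled per drift-estimation bin
#'   downstream (default 7, i.e. 56 trials per bin with 8 stimuli).
#' @param n_windows,window_mode sliding-window settings used downstream.
#' @param consensus_runs Louvain runs per window for the consensus
#'   partition in the pipeline (default 20).
#' @param tr_seconds scan repetition time (default 2).
#' @param seed RNG seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 40, n_nodes = 60, n_networks = 4,
                          scans_per_subject = 700, n_stimuli = 8,
                          n_repetitions = 98,
                          phase3_trials_per_condition = 96,
                          within_r_integrated = tanh(0.3),
                          between_r_integrated = 0.20,
                          within_r_segregated = tanh(0.8),
                          between_r_segregated = -0.05,
                          coupling_rho = -0.5, habit_rho = 0,
                          noise_sd = 0.2,
                          rate_mean = 16, rate_sd = 4.5,
                          exponent_mean = 0.38, exponent_sd = 0.16,
                          habit_mean = 0.13, habit_sd = 0.10,
                          v_max = 2.5, drift_alpha = 0.35,
                          a_mean = 1.2, a_sd = 0.08,
                          ter_mean = 0.30, ter_sd = 0.03,
                          phase3_v = 1.35,
                          segment_length_scans = 2,
                          midpoint_scale = 1.5,
                          behavior_bin_width = 7,
                          n_windows = 20,
                          window_mode = "non_overlapping",
                          consensus_runs = 20,
                          tr_seconds = 2, seed = 1L) {
  cfg <- as.list(environment())
  rs <- c(within_r_integrated, between_r_integrated,
          within_r_segregated, between_r_segregated)
  if (any(abs(rs) >= 1)) stop("cohort_config: correlations must be in (-1,1)")
  if (abs(coupling_rho) >= 1 || abs(habit_rho) >= 1) {
    stop("cohort_config: coupling/habit rho must be in (-1,1)")
  }
  if (!(within_r_segregated > within_r_integrated)) {
    stop("cohort_config: segregated state must have higher within-network r")
  }
  if (!(between_r_segregated < between_r_integrated)) {
    stop("cohort_config: segregated state must have lower between-network r")
  }
  counts <- c(n_nodes, n_networks, scans_per_subject, n_stimuli,
              n_repetitions, segment_length_scans, n_windows)
  if (any(counts <= 0) || n_subjects < 0) {
    stop("cohort_config: counts must be positive")
  }
  if (noise_sd <= 0) stop("cohort_config: noise_sd must be positive")
  cfg$trials_per_subject <- n_stimuli * n_repetitions +
    2 * phase3_trials_per_condition
  class(cfg) <- "cohort_config"
  cfg
}

#' Default atlas for a synthetic cohort
#'
#' Splits `n_nodes` into `n_networks` near-equal named networks.
#' @param config a `cohort_config`.
#' @return a `network_atlas`.
#' @export
default_atlas <- function(config) {
  net <- sort(rep_len(seq_len(config$n_networks), config$n_nodes))
  network_atlas(sprintf("node%03d", seq_len(config$n_nodes)),
                sprintf("N%02d", net))
}

#' Draw coupled subject-level ground-truth parameters
#'
#' Transition rate and learning exponent are drawn from a bivariate normal
#' with correlation `coupling_rho`; habit effect is drawn with correlation
#' `habit_rho` to both. DDM baselines (boundary, non-decision time) are
#' independent. Margins are clipped away from degenerate values (rates
#' below 0.5, exponents below 0.02, boundaries below 0.6, non-decision
#' times below 0.1 s); clipping is rare under the defaults.
#'
#' @param config a `cohort_config`.
#' @return data frame (one row per subject): `subject_id`,
#'   `transition_rate`, `learning_exponent`, `habit_effect`, `a`, `t_er`,
#'   `z`.
#' @export
draw_subject_parameters <- function(config) {
  n <- config$n_subjects
  empty <- data.frame(subject_id = character(0), transition_rate = numeric(0),
                      learning_exponent = numeric(0), habit_effect = numeric(0),
                      a = numeric(0), t_er = numeric(0), z = numeric(0))
  if (n == 0) return(empty)
  R <- matrix(c(1, config$coupling_rho, config$habit_rho,
                config$coupling_rho, 1, config$habit_rho,
                config$habit_rho, config$habit_rho, 1), 3, 3)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("draw_subject_parameters: rho combination is not a valid ",
         "correlation matrix")
  }
  Z <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = R)
  Z <- matrix(Z, ncol = 3)
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    transition_rate = pmax(0.5, config$rate_mean + config$rate_sd * Z[, 1]),
    learning_exponent = pmin(0.68, pmax(0.05, config$exponent_mean +
                                                    config$exponent_sd * Z[, 2])),
    habit_effect = config$habit_mean + config$habit_sd * Z[, 3],
    a = pmax(0.6, stats::rnorm(n, config$a_mean, config$a_sd)),
    t_er = pmax(0.1, stats::rnorm(n, config$ter_mean, config$ter_sd)),
    z = 0.5
  )
}

# nearest-PSD repair by eigenvalue clipping, rescaled to unit diagonal
psd_repair <- function(S, floor_ = 1e-8) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= floor_) return(S)
  vals <- pmax(e$values, floor_)
  S2 <- e$vectors %*% (t(e$vectors) * vals)
  S2 <- (S2 + t(S2)) / 2
  d <- sqrt(diag(S2))
  S2 <- S2 / outer(d, d)
  if (min(eigen(S2, symmetric = TRUE, only.values = TRUE)$values) < 0) {
    stop("psd_repair: positive semi-definite repair failed; min eigenvalue ",
         min(eigen(S2, symmetric = TRUE, only.values = TRUE)$values))
  }
  S2
}

#' Block correlation matrices of the two latent states
#'
#' Builds unit-diagonal block-structured correlation matrices (within-network
#' blocks at the state's within-network r, off-blocks at its between-network
#' r), each repaired to the nearest positive semi-definite correlation matrix
#' by eigenvalue clipping. The segregated state scores higher
#' [system_segregation()] by the config's invariants.
#'
#' @param atlas a `network_atlas`.
#' @param config a `cohort_config`.
#' @return list with `integrated` and `segregated` correlation matrices.
#' @export
build_state_covariances <- function(atlas, config) {
  same <- outer(atlas$network_of_node, atlas$network_of_node, "==")
  block <- function(w, b) {
    S <- ifelse(same, w, b)
    diag(S) <- 1
    psd_repair(S)
  }
  list(
    integrated = block(config$within_r_integrated,
                       config$between_r_integrated),
    segregated = block(config$within_r_segregated,
                       config$between_r_segregated)
  )
}

#' Segregated-state prevalence at a time point
#'
#' \eqn{P(\text{segregated at } u) = \mathrm{logis}(rate \cdot (u - m))}
#' with \eqn{u} the fraction of the session elapsed. By default the
#' midpoint is subject-specific, \eqn{m = c_0 / rate}, so all subjects
#' start near the same low prevalence and faster subjects complete the
#' integrated-to-segregated shift earlier; pass `midpoint` for a fixed
#' midpoint (e.g. `0.5` recovers a mid-session switch).
#'
#' @param u fraction of session elapsed, in \[0, 1\].
#' @param rate logistic steepness (transition rate).
#' @param midpoint fixed midpoint, or `NULL` for `midpoint_scale / rate`.
#' @param midpoint_scale constant `c0` (default 2).
#' @return probability of the segregated state.
#' @export
segregated_prevalence <- function(u, rate, midpoint = NULL,
                                  midpoint_scale = 2) {
  m <- if (is.null(midpoint)) {
    if (rate == 0) 0 else midpoint_scale / rate
  } else {
    midpoint
  }
  stats::plogis(rate * (u - m))
}

#' Simulate one subject's state-switching ROI time series
#'
#' Scans are partitioned into constant-state segments; each segment's state
#' is Bernoulli with the segregated-prevalence logistic evaluated at the
#' segment midpoint, and its samples are drawn from the state's covariance
#' plus isotropic noise. The realised state sequence is stored as ground
#' truth. Trial onsets are spread evenly over the scans.
#'
#' @param gt one row of [draw_subject_parameters()].
#' @param covs list from [build_state_covariances()].
#' @param config a `cohort_config`.
#' @param atlas a `network_atlas` (default [default_atlas()]).
#' @param midpoint optional fixed logistic midpoint (see
#'   [segregated_prevalence()]).
#' @return an `roi_timeseries` with extra fields `state_scan` (per-scan
#'   state: 1 integrated, 2 segregated) and `segments` (segment table).
#' @export
simulate_subject <- function(gt, covs, config, atlas = default_atlas(config),
                             midpoint = NULL) {
  n_scans <- config$scans_per_subject
  seg_len <- config$segment_length_scans
  if (n_scans < 2 * config$n_windows) {
    stop("simulate_subject: scans_per_subject must be at least twice ",
         "the number of windows")
  }
  starts <- seq(1, n_scans, by = seg_len)
  ends <- pmin(starts + seg_len - 1, n_scans)
  u_mid <- ((starts + ends) / 2) / n_scans
  p_seg <- segregated_prevalence(u_mid, gt$transition_rate, midpoint,
                                 config$midpoint_scale)
  seg_state <- 1L + as.integer(stats::runif(length(starts)) < p_seg)
  chol_int <- chol(covs$integrated)
  chol_seg <- chol(covs$segregated)
  X <- matrix(0, config$n_nodes, n_scans)
  for (i in seq_along(starts)) {
    len <- ends[i] - starts[i] + 1
    Lc <- if (seg_state[i] == 2L) chol_seg else chol_int
    X[, starts[i]:ends[i]] <-
      t(matrix(stats::rnorm(len * config$n_nodes), len) %*% Lc) +
      config$noise_sd * matrix(stats::rnorm(len * config$n_nodes),
                               config$n_nodes)
  }
  n_ph2 <- config$n_stimuli * config$n_repetitions
  onsets <- round(seq(1, n_scans, length.out = n_ph2))
  ts <- roi_timeseries(X, subject_id = gt$subject_id, atlas = atlas,
                       tr_seconds = config$tr_seconds,
                       repetition_onsets = onsets)
  ts$state_scan <- rep(seg_state, times = ends - starts + 1)
  ts$segments <- data.frame(start = starts, end = ends, u = u_mid,
                            p_segregated = p_seg, state = seg_state)
  ts
}

# drift power law: v_k = v_max * min(1, alpha * log(k+1)^b)
drift_power_law <- function(k, b, v_max, alpha) {
  v_max * pmin(1, alpha * log(k + 1)^b)
}

#' Simulate the cohort's behavioral trials
#'
#' Phase 2: for each stimulus and repetition k = 1..n_repetitions, the
#' drift follows the capped power law
#' \eqn{v_k = v_{max}\min(1, \alpha \log(k+1)^{b})} with the subject's
#' exponent `b`, so the learning-rate fitter's model family is exactly
#' realisable. Phase 3: compatible and incompatible drifts differ by the
#' subject's true habit effect, symmetric around `phase3_v`. All trials are
#' simulated with [simulate_ddm_trials()] and accuracy-coded.
#'
#' @param gt ground-truth table from [draw_subject_parameters()].
#' @param config a `cohort_config`.
#' @return trial-table data frame: `subject_id`, `phase`, `stimulus`,
#'   `repetition`, `condition`, `response`, `accuracy`, `rt_seconds`.
#' @export
simulate_behavior_cohort <- function(gt, config) {
  if (any(gt$a <= 0) || any(gt$t_er < 0)) {
    stop("simulate_behavior_cohort: non-positive a or negative t_er")
  }
  out <- vector("list", nrow(gt))
  for (i in seq_len(nrow(gt))) {
    g <- gt[i, ]
    reps <- seq_len(config$n_repetitions)
    vk <- drift_power_law(reps, g$learning_exponent, config$v_max,
                          config$drift_alpha)
    stim <- rep(seq_len(config$n_stimuli), each = config$n_repetitions)
    repn <- rep(reps, config$n_stimuli)
    cond2 <- ifelse(stim %% 2 == 1, "approach", "avoidance")
    ph2 <- simulate_ddm_trials(vk[repn], g$a, g$t_er, z = g$z)
    n3 <- config$phase3_trials_per_condition
    v_comp <- config$phase3_v + g$habit_effect / 2
    v_incomp <- config$phase3_v - g$habit_effect / 2
    ph3 <- simulate_ddm_trials(c(rep(v_comp, n3), rep(v_incomp, n3)),
                               g$a, g$t_er, z = g$z)
    out[[i]] <- rbind(
      data.frame(subject_id = g$subject_id, phase = 2L,
                 stimulus = stim[ph2$trial], repetition = repn[ph2$trial],
                 condition = cond2[ph2$trial], response = ph2$accuracy,
                 accuracy = ph2$accuracy, rt_seconds = ph2$rt),
      data.frame(subject_id = g$subject_id, phase = 3L,
                 stimulus = NA_integer_, repetition = NA_integer_,
                 condition = rep(c("compatible", "incompatible"),
                                 each = n3)[ph3$trial],
                 response = ph3$accuracy, accuracy = ph3$accuracy,
                 rt_seconds = ph3$rt)
    )
  }
  do.call(rbind, out)
}

#' Generate a full synthetic cohort
#'
#' Draws coupled subject parameters, builds the two state covariance
#' matrices, simulates every subject's time series and behavioral trials,
#' and optionally writes the cohort to delimited files (one time-series
#' file per subject, an atlas file, a trial table and the ground-truth
#' table). Identical seeds give bit-identical cohorts.
#'
#' @param config a `cohort_config`.
#' @param out_dir optional output directory.
#' @return list with `config`, `atlas`, `ground_truth`, `covariances`,
#'   `timeseries` (list of `roi_timeseries`), `trials`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  atlas <- default_atlas(config)
  covs <- build_state_covariances(atlas, config)
  gt <- draw_subject_parameters(config)
  ts_list <- lapply(seq_len(nrow(gt)), function(i) {
    simulate_subject(gt[i, ], covs, config, atlas)
  })
  names(ts_list) <- gt$subject_id
  trials <- simulate_behavior_cohort(gt, config)
  cohort <- list(config = config, atlas = atlas, ground_truth = gt,
                 covariances = covs, timeseries = ts_list, trials = trials)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_atlas(atlas, file.path(out_dir, "atlas.tsv"))
    utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    for (id in names(ts_list)) {
      write_timeseries(ts_list[[id]],
                       file.path(out_dir, paste0("timeseries_", id, ".tsv")))
    }
  }
  cohort
}
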