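#' Subject-level trajectory features from a Q (or metric) time course
#'
#' Ordinary-least-squares slope of the per-window metric on the logarithm of
#' the cumulative trial count at each window's midpoint, plus the mean over
#' the first three windows ("early" value).
#'
#' @param q_by_window numeric vector, one value per window (>= 4 windows,
#'   no missing values).
#' @param trial_counts cumulative trial count at each window midpoint
#'   (positive, same length).
#' @return list with `slope`, `early`, `intercept`.
#' @export
trajectory_features <- function(q_by_window, trial_counts) {
  if (length(q_by_window) < 4) {
    stop("trajectory_features: need at least 4 windows")
  }
  if (anyNA(q_by_window)) {
    stop("trajectory_features: missing windows: ",
         paste(which(is.na(q_by_window)), collapse = ", "))
  }
  stopifnot(length(trial_counts) == length(q_by_window),
            all(trial_counts > 0))
  x <- log(trial_counts)
  fit <- stats::lm.fit(cbind(1, x), q_by_window)
  list(slope = unname(fit$coefficients[2]),
       early = mean(q_by_window[1:3]),
       intercept = unname(fit$coefficients[1]))
}

# cumulative trial count at each window midpoint
window_trial_counts <- function(plan, onsets) {
  vapply(plan$windows$midpoint,
         function(m) sum(onsets <= m), numeric(1))
}

pearson_entry <- function(x, y, alternative = "two.sided") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), flagged = TRUE))
  }
  ct <- stats::cor.test(x[ok], y[ok], alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), flagged = FALSE)
}

#' Cohort-level brain-behaviour statistics
#'
#' Given per-subject summaries (after QC and outlier exclusion), computes:
#' a one-sample t test on the Q-slope betas; Pearson correlations of Q-slope
#' and early Q with learning rate (early-Q tests one-tailed, greater) and
#' habit strength; a paired t test of compatible vs incompatible drift; a
#' median split by learning rate with group mean Q curves (group sizes
#' differ by at most one); and, optionally, Welch t tests against a second
#' cohort. Zero-variance correlates are flagged and the rest computed.
#'
#' @param summaries data frame with one row per retained subject: columns
#'   `q_slope`, `early_q`, `learning_rate`, `habit_strength`, optionally
#'   `v_compatible`, `v_incompatible`.
#' @param q_curves optional subjects-by-windows matrix of Q values for the
#'   median-split group curves.
#' @param other optional second cohort's summaries for Welch t tests.
#' @return a `stats_report` list.
#' @export
cohort_statistics <- function(summaries, q_curves = NULL, other = NULL) {
  if (nrow(summaries) < 5) {
    stop("cohort_statistics: need >= 5 subjects after exclusions")
  }
  tt <- stats::t.test(summaries$q_slope)
  rep_ <- list(
    n = nrow(summaries),
    q_slope_t = list(t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, mean = mean(summaries$q_slope)),
    r_qslope_learning = pearson_entry(summaries$q_slope,
                                      summaries$learning_rate),
    r_qslope_habit = pearson_entry(summaries$q_slope,
                                   summaries$habit_strength),
    r_earlyq_learning = pearson_entry(summaries$early_q,
                                      summaries$learning_rate,
                                      alternative = "greater"),
    r_earlyq_habit = pearson_entry(summaries$early_q,
                                   summaries$habit_strength)
  )
  if (all(c("v_compatible", "v_incompatible") %in% names(summaries))) {
    ok <- stats::complete.cases(summaries[, c("v_compatible",
                                              "v_incompatible")])
    pt <- stats::t.test(summaries$v_compatible[ok],
                        summaries$v_incompatible[ok], paired = TRUE)
    rep_$drift_paired_t <- list(t = unname(pt$statistic),
                                df = unname(pt$parameter), p = pt$p.value)
  }
  # median split by learning rate into near-equal groups (rank-based so the
  # sizes differ by at most one regardless of ties)
  rk <- rank(summaries$learning_rate, ties.method = "first")
  fast <- rk > stats::median(rk)
  rep_$median_split <- list(
    n_fast = sum(fast), n_slow = sum(!fast),
    fast_mean_learning_rate = mean(summaries$learning_rate[fast]),
    slow_mean_learning_rate = mean(summaries$learning_rate[!fast])
  )
  if (!is.null(q_curves)) {
    rep_$median_split$fast_q_curve <-
      colMeans(q_curves[fast, , drop = FALSE])
    rep_$median_split$slow_q_curve <-
      colMeans(q_curves[!fast, , drop = FALSE])
  }
  if (!is.null(other)) {
    wt <- stats::t.test(summaries$q_slope, other$q_slope)
    wl <- stats::t.test(summaries$learning_rate, other$learning_rate)
    rep_$welch_between_cohorts <- list(
      q_slope = list(t = unname(wt$statistic), df = unname(wt$parameter),
                     p = wt$p.value),
      learning_rate = list(t = unname(wl$statistic),
                           df = unname(wl$parameter), p = wl$p.value)
    )
  }
  class(rep_) <- "stats_report"
  rep_
}

#' Cartographic profile of per-network PC/MDZ slopes
#'
#' Projects each network's mean participation-coefficient slope and mean
#' module-degree-z slope across subjects into a 2-D profile, with one-sample
#' t tests per network and axis, family-wise-error corrected (Bonferroni
#' across networks x metrics).
#'
#' @param pc_slopes,mdz_slopes subjects-by-networks matrices of per-subject
#'   slopes (columns named by network).
#' @return data frame: `network`, `mean_pc_slope`, `mean_mdz_slope`, t
#'   statistics and raw and FWE-adjusted p values per axis.
#' @export
cartography_profile <- function(pc_slopes, mdz_slopes) {
  stopifnot(ncol(pc_slopes) == ncol(mdz_slopes))
  nets <- colnames(pc_slopes)
  if (is.null(nets)) nets <- paste0("N", seq_len(ncol(pc_slopes)))
  one <- function(x) {
    if (length(x) < 2 || stats::sd(x) == 0) {
      if (all(x == 0)) return(list(t = 0, p = 1))
      return(list(t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x)
    list(t = unname(tt$statistic), p = tt$p.value)
  }
  pc <- lapply(seq_along(nets), function(j) one(pc_slopes[, j]))
  mdz <- lapply(seq_along(nets), function(j) one(mdz_slopes[, j]))
  raw_p <- c(vapply(pc, `[[`, numeric(1), "p"),
             vapply(mdz, `[[`, numeric(1), "p"))
  adj_p <- stats::p.adjust(raw_p, method = "bonferroni")
  m <- length(nets)
  data.frame(
    network = nets,
    mean_pc_slope = colMeans(pc_slopes),
    mean_mdz_slope = colMeans(mdz_slopes),
    t_pc = vapply(pc, `[[`, numeric(1), "t"),
    p_pc = raw_p[seq_len(m)],
    p_pc_fwe = adj_p[seq_len(m)],
    t_mdz = vapply(mdz, `[[`, numeric(1), "t"),
    p_mdz = raw_p[m + seq_len(m)],
    p_mdz_fwe = adj_p[m + seq_len(m)],
    row.names = NULL
  )
}

#' Run the full segregation-dynamics pipeline on a synthetic cohort
#'
#' Executes simulate, prep (task-regressor + high-pass residualisation), FC
#' (tapered windows), state clustering and prevalence, per-window consensus
#' modularity and cartography, behavioral fits, and the cohort statistics
#' battery. All randomness flows from `config$seed`, so re-running with the
#' same config is bit-identical. With `out_dir` given, the tables and a
#' machine-readable JSON report are written alongside a plain-text log.
#'
#' @param config a `cohort_config` (or path to a YAML file readable by
#'   [read_pipeline_config()]).
#' @param out_dir optional output directory.
#' @param skip_behavior omit the behavioral fits and the brain-behaviour
#'   battery.
#' @param cartography compute per-window node cartography and per-network
#'   slopes (the slowest stage after modularity); disable when only the
#'   Q-trajectory and behavioral features are needed.
#' @param states run the brain-state clustering and prevalence stage
#'   (disable for Q-trajectory-only replications).
#' @return a list with `cohort`, `prevalence`, `q_table`, `summaries`,
#'   `stats`, `profile`, and bookkeeping fields.
#' @export
run_pipeline <- function(config, out_dir = NULL, skip_behavior = FALSE,
                         cartography = TRUE, states = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "cohort_config"))
  stage <- "simulate"
  res <- tryCatch({
    cohort <- simulate_cohort(config)
    atlas <- cohort$atlas

    stage <- "prep"
    prepped <- lapply(cohort$timeseries, function(ts) {
      design <- build_fourier_design(ts$repetition_onsets, ts$tr_seconds,
                                     ncol(ts$data))
      regress_confounds(ts, design)
    })

    stage <- "fc"
    plan <- plan_windows(config$scans_per_subject, config$n_windows,
                         config$window_mode)
    fcs <- lapply(prepped, windowed_fc_stack, plan = plan)

    stage <- "states"
    model <- NULL
    prevalence <- NULL
    if (states) {
      model <- cluster_states(fcs, k = 2, replicates = 10)
      prevalence <- label_and_prevalence(model, atlas)
    }

    stage <- "modularity"
    n_sub <- length(fcs)
    q_mat <- matrix(NA_real_, n_sub, config$n_windows,
                    dimnames = list(names(fcs), NULL))
    nets <- atlas$networks
    pc_slopes <- matrix(NA_real_, n_sub, length(nets),
                        dimnames = list(names(fcs), nets))
    mdz_slopes <- pc_slopes
    trial_counts <- window_trial_counts(
      plan, cohort$timeseries[[1]]$repetition_onsets)
    for (i in seq_len(n_sub)) {
      pc_by_win <- matrix(NA_real_, config$n_windows, length(nets))
      mdz_by_win <- pc_by_win
      for (w in seq_len(config$n_windows)) {
        part <- consensus_partition(fcs[[i]]$z[[w]],
                                    n_runs = config$consensus_runs)
        q_mat[i, w] <- part$Q
        if (cartography) {
          carto <- node_cartography(fcs[[i]]$z[[w]], part)
          ns <- network_summarize(carto, atlas)
          pc_by_win[w, ] <- ns$mean_pc
          mdz_by_win[w, ] <- ns$mean_mdz
        }
      }
      if (cartography) {
        for (j in seq_along(nets)) {
          pc_slopes[i, j] <-
            trajectory_features(pc_by_win[, j], trial_counts)$slope
          mdz_slopes[i, j] <-
            trajectory_features(mdz_by_win[, j], trial_counts)$slope
        }
      }
    }

    stage <- "behavior"
    gt <- cohort$ground_truth
    summaries <- data.frame(subject_id = gt$subject_id)
    for (i in seq_len(n_sub)) {
      feats <- trajectory_features(q_mat[i, ], trial_counts)
      summaries$q_slope[i] <- feats$slope
      summaries$early_q[i] <- feats$early
    }
    if (!skip_behavior) {
      for (i in seq_len(n_sub)) {
        tr <- cohort$trials[cohort$trials$subject_id == gt$subject_id[i], ]
        ph2 <- tr[tr$phase == 2, ]
        ph2 <- data.frame(repetition = ph2$repetition,
                          accuracy = ph2$accuracy, rt = ph2$rt_seconds)
        curve <- drift_curve(ph2, bin_width = config$behavior_bin_width,
                             n_repetitions = config$n_repetitions)
        summaries$learning_rate[i] <-
          fit_learning_rate(curve)$learning_rate
        ph3 <- tr[tr$phase == 3, ]
        ph3 <- data.frame(condition = ph3$condition,
                          accuracy = ph3$accuracy, rt = ph3$rt_seconds)
        hb <- habit_strength(ph3)
        summaries$habit_strength[i] <- hb$habit_strength
        summaries$v_compatible[i] <- hb$v_compatible
        summaries$v_incompatible[i] <- hb$v_incompatible
      }
      summaries$habit_outlier <- flag_outliers(summaries$habit_strength)
    }

    stage <- "statistics"
    retained <- if (skip_behavior) summaries
                else summaries[!summaries$habit_outlier, ]
    stats_rep <- if (skip_behavior) NULL else {
      cohort_statistics(retained,
                        q_curves = q_mat[!summaries$habit_outlier, ,
                                         drop = FALSE])
    }
    profile <- if (cartography) cartography_profile(pc_slopes, mdz_slopes)
               else NULL

    list(config = config, cohort = cohort, plan = plan,
         state_model = model, prevalence = prevalence,
         q_table = q_mat, trial_counts = trial_counts,
         pc_slopes = pc_slopes, mdz_slopes = mdz_slopes,
         summaries = summaries, retained = retained,
         stats = stats_rep, profile = profile)
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds any subset of [cohort_config()]'s arguments.
#' @param path YAML file path.
#' @return a `cohort_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(cohort_config)))
  do.call(cohort_config, vals[keep])
}

#' Write pipeline outputs to a directory
#'
#' Comma-delimited tables (subject summaries, per-window Q, prevalence,
#' cartography profile), a JSON statistics report, and a plain-text log
#' with the seed and package version. The JSON report contains no
#' timestamps, so identical runs produce byte-identical reports.
#'
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$summaries, file.path(out_dir, "subject_summaries.csv"),
                   row.names = FALSE)
  q_df <- data.frame(subject_id = rownames(res$q_table), res$q_table,
                     check.names = FALSE)
  utils::write.csv(q_df, file.path(out_dir, "q_by_window.csv"),
                   row.names = FALSE)
  utils::write.csv(res$prevalence$prevalence,
                   file.path(out_dir, "state_prevalence.csv"),
                   row.names = FALSE)
  if (!is.null(res$profile)) {
    utils::write.csv(res$profile,
                     file.path(out_dir, "cartography_profile.csv"),
                     row.names = FALSE)
  }
  report <- list(config = unclass(res$config),
                 state_labels = res$prevalence$labels,
                 centroid_segregation = res$prevalence$segregation,
                 stats = if (is.null(res$stats)) NULL else unclass(res$stats))
  jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(paste("seed:", res$config$seed),
               paste("package:", "segdyn",
                     as.character(utils::packageVersion("segdyn"))),
               paste("generated:", format(Sys.time(), tz = "UTC"))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
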