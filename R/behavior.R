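#' Simulate two-choice drift-diffusion trials
#'
#' Forward-simulates the two-boundary diffusion process (boundaries 0 and
#' `a`, start `z * a`, diffusion scale `s = 1`) by Euler-Maruyama with
#' dt = 1 ms and within-step diffusion-bridge crossing correction. Accuracy
#' is coded 1 on upper-boundary absorption; RT is the passage time plus the
#' non-decision time `t_er`. Trials not absorbed within 10 s are treated as
#' omissions and excluded (count reported via a message).
#'
#' @param v drift rate (evidence/s); may be a vector of per-trial drifts.
#' @param a boundary separation (> 0).
#' @param t_er non-decision time in seconds (>= 0).
#' @param n_trials number of trials (ignored when `v` is a vector).
#' @param z starting point as a fraction of `a` (default 0.5).
#' @param dt Euler step in seconds (default 0.001).
#' @return data frame with `trial`, `drift`, `accuracy`, `rt`.
#' @export
simulate_ddm_trials <- function(v, a, t_er, n_trials = length(v), z = 0.5,
                                dt = 0.001) {
  if (a <= 0 || t_er < 0) stop("simulate_ddm_trials: need a > 0, t_er >= 0")
  if (z <= 0 || z >= 1) stop("simulate_ddm_trials: z must be in (0,1)")
  if (length(v) == 1) v <- rep(v, n_trials)
  rt <- numeric(length(v))
  acc <- integer(length(v))
  # group identical drifts so the compiled sampler is called per drift value
  for (vv in unique(v)) {
    idx <- which(v == vv)
    sim <- .ddm_fp_sim(length(idx), vv, a, t_er, z, 1.0, dt, 10.0)
    rt[idx] <- sim$rt
    acc[idx] <- sim$accuracy
  }
  out <- data.frame(trial = seq_along(v), drift = v, accuracy = acc, rt = rt)
  n_omit <- sum(is.na(out$rt))
  if (n_omit > 0) {
    message("simulate_ddm_trials: ", n_omit, " omission(s) beyond 10 s cutoff")
    out <- out[!is.na(out$rt), ]
  }
  out
}

#' Closed-form (EZ) drift-diffusion parameter estimation
#'
#' Moment inversion from accuracy, correct-RT mean and correct-RT variance
#' to drift `v`, boundary `a` and non-decision time `t_er`, assuming an
#' unbiased start (z = 0.5) and diffusion scale s = 1. Edge-corrected
#' accuracy \eqn{p^* = (x + 0.5)/(n + 1)} replaces p when p is exactly 0,
#' 0.5 or 1. All-error subsets yield a negative drift by the accuracy-coding
#' symmetry; degenerate RT variance returns flagged `NA` parameters.
#'
#' @param trials data frame with `accuracy` (0/1) and `rt` (seconds), or the
#'   output of [simulate_ddm_trials()].
#' @param min_trials minimum trials required (default 20).
#' @return list with `v`, `a`, `t_er`, `n`, `p_correct`.
#' @export
ez_fit <- function(trials, min_trials = 20) {
  rt <- trials$rt
  acc <- trials$accuracy
  n <- length(rt)
  if (n < min_trials) stop("ez_fit: fewer than ", min_trials, " trials")
  x <- sum(acc == 1)
  p <- x / n
  if (p %in% c(0, 0.5, 1)) p <- (x + 0.5) / (n + 1)
  use <- if (p >= 0.5) acc == 1 else acc == 0 # RT moments of the modal choice
  mrt <- mean(rt[use])
  vrt <- stats::var(rt[use])
  if (!is.finite(vrt) || vrt <= 0) {
    warning("ez_fit: degenerate RT variance; returning NA parameters")
    return(list(v = NA_real_, a = NA_real_, t_er = NA_real_, n = n,
                p_correct = x / n))
  }
  s <- 1
  pp <- max(p, 1 - p) # invert for the dominant boundary, then restore sign
  L <- stats::qlogis(pp)
  xx <- L * (L * pp^2 - L * pp + pp - 0.5) / vrt
  v_mag <- s * xx^(1 / 4)
  a <- s^2 * L / v_mag
  y <- -v_mag * a / s^2
  mdt <- (a / (2 * v_mag)) * (1 - exp(y)) / (1 + exp(y))
  list(v = if (p >= 0.5) v_mag else -v_mag, a = a, t_er = mrt - mdt, n = n,
       p_correct = x / n)
}

#' Drift-rate learning curve across stimulus repetitions
#'
#' Pools phase-2 trials across stimuli into consecutive repetition bins of
#' `bin_width` repetitions and estimates the drift rate of each bin with
#' [ez_fit()]. Bins with fewer than `min_trials` trials are dropped with a
#' warning.
#'
#' @param trials phase-2 trial table with columns `repetition`, `accuracy`,
#'   `rt`.
#' @param bin_width repetitions per bin (default 7).
#' @param n_repetitions total repetitions per stimulus (default 98).
#' @param min_trials minimum trials per bin (default 20).
#' @return a `learning_curve`: data frame with `bin`, `k` (bin-centre
#'   repetition), `v`, `n_trials`.
#' @export
drift_curve <- function(trials, bin_width = 7, n_repetitions = 98,
                        min_trials = 20) {
  reps <- sort(unique(trials$repetition))
  missing_reps <- setdiff(seq_len(n_repetitions), reps)
  if (length(missing_reps) > 0) {
    message("drift_curve: ", length(missing_reps), " repetition(s) absent")
  }
  breaks <- seq(1, n_repetitions + bin_width, by = bin_width)
  bin_of <- findInterval(trials$repetition, breaks)
  out <- do.call(rbind, lapply(sort(unique(bin_of)), function(b) {
    sub <- trials[bin_of == b, ]
    if (nrow(sub) < min_trials) {
      warning("drift_curve: bin ", b, " below ", min_trials,
              " trials; dropped")
      return(NULL)
    }
    fit <- ez_fit(sub, min_trials)
    data.frame(bin = b, k = mean(range(trials$repetition[bin_of == b])),
               v = fit$v, n_trials = nrow(sub))
  }))
  if (is.null(out) || nrow(out) == 0) {
    stop("drift_curve: no repetition bin reaches ", min_trials,
         " trials; widen bin_width")
  }
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' Learning rate from a drift-rate curve (robust power fit)
#'
#' Fits the one-term power function \eqn{v_k \approx \alpha x_k^b} with
#' \eqn{x_k = \log(k + 1)} (log repetition, shifted so the first repetition
#' is informative) to the binned drift curve, and returns the learning rate
#' \eqn{-b}. The default `"LAR"` method minimises absolute residuals of the
#' linearised model \eqn{\log v = \log\alpha + b \log x} by iteratively
#' reweighted least squares, protecting the exponent against gross outlier
#' bins; `"LS"` is plain least squares on the same linearisation.
#' Non-positive drift estimates cannot enter the log fit and are dropped
#' with a warning.
#'
#' @param curve a `learning_curve` from [drift_curve()] (needs `k`, `v`).
#' @param method `"LAR"` (default) or `"LS"`.
#' @return list with `learning_rate` (= -b), `exponent` (b),
#'   `coefficient` (alpha), `method`, `converged`.
#' @export
fit_learning_rate <- function(curve, method = c("LAR", "LS")) {
  method <- match.arg(method)
  ok <- is.finite(curve$v) & curve$v > 0
  if (any(!ok)) {
    warning("fit_learning_rate: dropped ", sum(!ok),
            " non-positive/missing drift point(s)")
  }
  k <- curve$k[ok]
  v <- curve$v[ok]
  if (length(v) < 3) stop("fit_learning_rate: need >= 3 curve points")
  lx <- log(log(k + 1))
  ly <- log(v)
  converged <- TRUE
  ls_coefs <- unname(stats::lm.fit(cbind(1, lx), ly)$coefficients)
  if (method == "LS") {
    coefs <- ls_coefs
  } else {
    # least-absolute-residuals: IRLS polish from the LS start, then direct
    # Nelder-Mead descent on the L1 objective (IRLS alone can cycle between
    # vertices of the piecewise-linear objective); keep the best candidate
    l1 <- function(th) sum(abs(ly - th[1] - th[2] * lx))
    irls <- ls_coefs
    for (iter in seq_len(25)) {
      w <- 1 / pmax(abs(ly - irls[1] - irls[2] * lx), 1e-8)
      irls <- unname(stats::lm.wfit(cbind(1, lx), ly, w)$coefficients)
    }
    opt <- tryCatch(
      stats::optim(irls, l1, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12)),
      error = function(e) NULL)
    cands <- list(ls_coefs, irls)
    if (!is.null(opt) && all(is.finite(opt$par))) {
      cands <- c(cands, list(unname(opt$par)))
    } else {
      warning("fit_learning_rate: LAR did not converge; ",
              "falling back to least squares")
      converged <- FALSE
    }
    coefs <- cands[[which.min(vapply(cands, l1, numeric(1)))]]
  }
  b <- unname(coefs[2])
  list(learning_rate = -b, exponent = b,
       coefficient = exp(unname(coefs[1])), method = method,
       converged = converged)
}

#' Habit strength from the goal-habit competition phase
#'
#' Fits [ez_fit()] separately to the compatible and incompatible phase-3
#' trials and returns the drift-rate difference
#' \eqn{v_{compatible} - v_{incompatible}}. Conditions with fewer than
#' `min_trials` trials yield a flagged `NA`.
#'
#' @param trials phase-3 trial table with columns `condition`
#'   (`"compatible"`/`"incompatible"`), `accuracy`, `rt`.
#' @param min_trials minimum trials per condition (default 20).
#' @return list with `habit_strength`, `v_compatible`, `v_incompatible`.
#' @export
habit_strength <- function(trials, min_trials = 20) {
  conds <- c("compatible", "incompatible")
  if (!all(conds %in% trials$condition)) {
    stop("habit_strength: both compatible and incompatible trials required")
  }
  vs <- vapply(conds, function(cc) {
    sub <- trials[trials$condition == cc, ]
    if (nrow(sub) < min_trials) {
      warning("habit_strength: fewer than ", min_trials, " ", cc,
              " trials; flagged NA")
      return(NA_real_)
    }
    ez_fit(sub, min_trials)$v
  }, numeric(1))
  list(habit_strength = unname(vs[1] - vs[2]),
       v_compatible = unname(vs[1]), v_incompatible = unname(vs[2]))
}

#' Flag cohort-level habit-strength outliers
#'
#' Flags values more than `n_sd` standard deviations from the cohort mean
#' (the 3-SD discard rule applied before cohort statistics).
#'
#' @param values numeric vector of per-subject habit strengths.
#' @param n_sd threshold in standard deviations (default 3).
#' @return logical vector: `TRUE` = outlier.
#' @export
flag_outliers <- function(values, n_sd = 3) {
  mu <- mean(values, na.rm = TRUE)
  sdv <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(sdv) || sdv == 0) return(rep(FALSE, length(values)))
  abs(values - mu) > n_sd * sdv
}
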