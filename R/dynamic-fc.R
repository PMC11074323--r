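#' Plan tapered sliding windows over a scan series
#'
#' Divides a subject's `n_scans` scans into `n_windows` sliding windows.
#' In `"non_overlapping"` mode the series is split into contiguous windows of
#' length `floor(n_scans / n_windows)`, with the remainder scans given one
#' each to the earliest windows. In `"half_overlap"` mode windows of length
#' `floor(2 * n_scans / (n_windows + 1))` advance by half a window, the last
#' window's end clamped to the series; this yields the same window count from
#' a series roughly half as long.
#'
#' @param n_scans number of scans in the series.
#' @param n_windows number of windows (default 20).
#' @param mode `"non_overlapping"` or `"half_overlap"`.
#' @param taper_theta taper decay constant in scans; default a third of the
#'   window length (set per window for unequal windows). `Inf` gives a flat
#'   (uniform) window.
#' @return A `window_plan`: list with `n_windows`, `mode`, and a data frame
#'   `windows` with columns `start`, `end` (1-based, inclusive), `length`,
#'   `theta`, `midpoint`.
#' @export
plan_windows <- function(n_scans, n_windows = 20,
                         mode = c("non_overlapping", "half_overlap"),
                         taper_theta = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_windows >= 1)
  if (n_scans < 2 * n_windows) {
    stop("plan_windows: need at least ", 2 * n_windows,
         " scans for ", n_windows, " windows (got ", n_scans, ")")
  }
  if (mode == "non_overlapping") {
    base_len <- n_scans %/% n_windows
    rem <- n_scans %% n_windows
    len <- rep(base_len, n_windows)
    if (rem > 0) len[seq_len(rem)] <- base_len + 1
    end <- cumsum(len)
    start <- end - len + 1
  } else {
    T_len <- (2 * n_scans) %/% (n_windows + 1)
    step <- T_len %/% 2
    start <- 1 + step * (seq_len(n_windows) - 1)
    end <- pmin(start + T_len - 1, n_scans)
    len <- end - start + 1
  }
  theta <- if (is.null(taper_theta)) len / 3 else rep(taper_theta, n_windows)
  plan <- list(
    n_windows = n_windows,
    mode = mode,
    windows = data.frame(
      window = seq_len(n_windows),
      start = start, end = end, length = len,
      theta = theta, midpoint = (start + end) / 2
    )
  )
  class(plan) <- "window_plan"
  plan
}

#' Exponential taper weights for one window
#'
#' Weight vector \eqn{w_t = w_0 e^{(t - T)/\theta}}, \eqn{t = 1, \dots, T},
#' with \eqn{w_0 = (1 - e^{-1/\theta}) / (1 - e^{-T/\theta})} so the weights
#' sum to one exactly (geometric series). Weights increase towards the window
#' end, down-weighting distant scans; `theta = Inf` gives uniform `1/T`.
#'
#' @param T_len window length in scans (>= 2).
#' @param theta decay constant in scans (> 0); default `T_len / 3`.
#' @return numeric vector of length `T_len` summing to 1.
#' @export
taper_weights <- function(T_len, theta = T_len / 3) {
  stopifnot(T_len >= 2)
  if (!is.finite(theta)) return(rep(1 / T_len, T_len))
  if (theta <= 0) stop("taper_weights: theta must be positive")
  t <- seq_len(T_len)
  w0 <- (1 - exp(-1 / theta)) / (1 - exp(-T_len / theta))
  w0 * exp((t - T_len) / theta)
}

#' Weighted Pearson correlation
#'
#' \deqn{r_w = \frac{\sum_t w_t (x_t - \bar x)(y_t - \bar y)}
#'   {\sqrt{\sum_t w_t (x_t-\bar x)^2}\sqrt{\sum_t w_t (y_t-\bar y)^2}}}
#' with weighted means \eqn{\bar x = \sum_t w_t x_t / \sum_t w_t}. Returns
#' `NA` (with a warning) if either series has zero weighted variance.
#'
#' @param x,y numeric series of equal length.
#' @param w non-negative weights, same length.
#' @return correlation in \[-1, 1\], or `NA` if undefined.
#' @export
weighted_correlation <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  sw <- sum(w)
  xc <- x - sum(w * x) / sw
  yc <- y - sum(w * y) / sw
  vx <- sum(w * xc^2)
  vy <- sum(w * yc^2)
  if (vx <= 0 || vy <= 0) {
    warning("weighted_correlation: zero weighted variance; returning NA")
    return(NA_real_)
  }
  r <- sum(w * xc * yc) / sqrt(vx * vy)
  min(1, max(-1, r))
}

# weighted correlation matrix of nodes x scans data (rows = nodes)
weighted_corr_matrix <- function(X, w) {
  sw <- sum(w)
  mu <- as.vector(X %*% w) / sw
  Xc <- X - mu
  C <- Xc %*% (t(Xc) * w)
  d <- diag(C)
  bad <- d <= 0
  d[bad] <- 1
  R <- C / sqrt(outer(d, d))
  R[R > 1] <- 1
  R[R < -1] <- -1
  if (any(bad)) {
    R[bad, ] <- NA_real_
    R[, bad] <- NA_real_
  }
  diag(R) <- 1
  R
}

#' Windowed tapered functional-connectivity stack
#'
#' For each planned window, computes the weighted Pearson correlation between
#' every node pair using that window's exponential taper, then Fisher
#' z-transforms (`atanh`) the matrix with \eqn{|r|} clipped at
#' \eqn{1 - 10^{-7}}. Nodes with zero weighted variance in a window produce a
#' flagged (`NA`) row/column and a warning naming the window.
#'
#' @param ts an `roi_timeseries` (see [roi_timeseries()]) or a plain
#'   nodes-by-scans numeric matrix.
#' @param plan a `window_plan` from [plan_windows()].
#' @return A `windowed_fc`: list with `subject_id`, `z` (list of
#'   nodes-by-nodes Fisher-z matrices, one per window), and `windows`
#'   (the plan's window table).
#' @export
windowed_fc_stack <- function(ts, plan) {
  X <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  subject_id <- if (inherits(ts, "roi_timeseries")) ts$subject_id else NA
  stopifnot(inherits(plan, "window_plan"))
  if (max(plan$windows$end) > ncol(X)) {
    stop("windowed_fc_stack: plan exceeds series length")
  }
  zs <- vector("list", plan$n_windows)
  for (wi in seq_len(plan$n_windows)) {
    win <- plan$windows[wi, ]
    w <- taper_weights(win$length, win$theta)
    R <- weighted_corr_matrix(X[, win$start:win$end, drop = FALSE], w)
    if (anyNA(R)) {
      warning("windowed_fc_stack: undefined correlations in window ", wi)
    }
    clip <- 1 - 1e-7
    R[R > clip] <- clip
    R[R < -clip] <- -clip
    Z <- atanh(R)
    diag(Z) <- 0
    dimnames(Z) <- list(rownames(X), rownames(X))
    zs[[wi]] <- Z
  }
  structure(
    list(subject_id = subject_id, z = zs, windows = plan$windows),
    class = "windowed_fc"
  )
}
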