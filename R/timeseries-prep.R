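#' Fourier (sine) task-regressor design matrix
#'
#' Builds 14 sine-wave regressors spanning a 30-s post-onset window,
#' time-locked to trial onsets: column \eqn{j} holds
#' \eqn{\sin(\pi j \tau / 30)} at post-onset lag \eqn{\tau} seconds, summed
#' over events and zero elsewhere. A leading constant column is included.
#'
#' @param onsets trial-onset scan indices (1-based), non-empty, within the
#'   series.
#' @param tr scan repetition time in seconds.
#' @param n_scans number of scans.
#' @param n_basis number of sine harmonics (default 14).
#' @param span_seconds post-onset span covered (default 30).
#' @return `n_scans` x `(n_basis + 1)` matrix; first column the constant.
#' @export
build_fourier_design <- function(onsets, tr, n_scans, n_basis = 14,
                                 span_seconds = 30) {
  if (length(onsets) == 0) stop("build_fourier_design: no onsets given")
  onsets <- as.integer(onsets)
  if (any(onsets < 1 | onsets > n_scans)) {
    stop("build_fourier_design: onsets outside the series")
  }
  X <- matrix(0, n_scans, n_basis)
  n_lags <- floor(span_seconds / tr)
  for (on in onsets) {
    scans <- on + 0:n_lags
    keep <- scans <= n_scans
    tau <- (scans[keep] - on) * tr
    for (j in seq_len(n_basis)) {
      X[scans[keep], j] <- X[scans[keep], j] + sin(pi * j * tau / span_seconds)
    }
  }
  cbind(constant = 1, X)
}

# discrete-cosine drift basis implementing a GLM-embedded high-pass filter:
# columns cos(pi * k * (t - 1/2) / n) for periods 2n*tr/k above the cutoff
dct_highpass_basis <- function(n_scans, tr, cutoff_seconds = 128) {
  if (!is.finite(cutoff_seconds) || cutoff_seconds <= 0) {
    return(matrix(numeric(0), n_scans, 0))
  }
  k_max <- floor(2 * n_scans * tr / cutoff_seconds)
  if (k_max < 1) return(matrix(numeric(0), n_scans, 0))
  t <- seq_len(n_scans) - 0.5
  vapply(seq_len(k_max),
         function(k) cos(pi * k * t / n_scans),
         numeric(n_scans))
}

#' Regress task activity and confounds out of ROI time series
#'
#' Per node, returns ordinary-least-squares residuals after projecting out
#' the supplied design together with a discrete-cosine high-pass drift basis
#' up to `highpass_seconds` (the GLM-embedded equivalent of a 128-s cutoff).
#' Collinear design columns are dropped with a warning. Residuals are
#' orthogonal to the retained design and the operation is idempotent.
#'
#' @param ts an `roi_timeseries` or nodes-by-scans matrix.
#' @param design scans-by-columns design matrix (e.g. from
#'   [build_fourier_design()], possibly with confound columns appended); a
#'   constant column is added if absent.
#' @param highpass_seconds high-pass cutoff in seconds (default 128;
#'   `Inf` disables).
#' @return object of the same type with residual data.
#' @export
regress_confounds <- function(ts, design, highpass_seconds = 128) {
  X <- if (inherits(ts, "roi_timeseries")) ts$data else as.matrix(ts)
  design <- as.matrix(design)
  if (nrow(design) != ncol(X)) {
    stop("regress_confounds: design rows must equal scans")
  }
  tr <- if (inherits(ts, "roi_timeseries")) ts$tr_seconds else 1
  D <- cbind(design, dct_highpass_basis(ncol(X), tr, highpass_seconds))
  if (!any(apply(D, 2, function(col) all(col == col[1]) && col[1] != 0))) {
    D <- cbind(1, D)
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("regress_confounds: rank-deficient design; dropped ",
            ncol(D) - qrD$rank, " collinear column(s)")
  }
  resid <- t(qr.resid(qrD, t(X)))
  if (inherits(ts, "roi_timeseries")) {
    out <- ts
    out$data <- resid
    out
  } else {
    resid
  }
}

#' Motion-based subject exclusion
#'
#' A subject is excluded when the fraction of scans with frame-wise
#' displacement (FD) strictly above `fd_threshold` exceeds `max_fraction`
#' (strict inequality: exactly the limit fraction is retained).
#'
#' @param fd_trace per-scan FD in millimetres (non-negative, non-empty).
#' @param fd_threshold spike threshold in mm (default 0.2).
#' @param max_fraction tolerated spike fraction (default 0.2).
#' @param subject_id optional identifier carried into the report.
#' @return a `qc_report`: list with `subject_id`, `spike_fraction`,
#'   `excluded`.
#' @export
qc_motion_exclude <- function(fd_trace, fd_threshold = 0.2,
                              max_fraction = 0.2, subject_id = NA) {
  if (length(fd_trace) == 0) stop("qc_motion_exclude: empty FD trace")
  if (any(fd_trace < 0)) stop("qc_motion_exclude: FD must be non-negative")
  spike_fraction <- mean(fd_trace > fd_threshold)
  structure(
    list(subject_id = subject_id, spike_fraction = spike_fraction,
         excluded = spike_fraction > max_fraction),
    class = "qc_report"
  )
}
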