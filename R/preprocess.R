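#' Temporal band-pass filter a grid of time series
#'
#' Applies a zero-phase band-pass to every masked pixel series. Resting-state
#' functional connectivity lives in slow BOLD fluctuations, conventionally
#' 0.009 Hz < f < 0.08 Hz; the defaults select that band. The default filter
#' is a 4th-order Butterworth run forward and backward
#' ([signal::filtfilt()]), which doubles the effective order and cancels
#' phase lag so that correlations downstream are not distorted by filter
#' delay. An ideal FFT-mask filter (hard frequency cut, also zero phase) is
#' available as an alternative. Each series is demeaned first; DC is outside
#' the passband, so output series are (near) zero mean.
#'
#' @param grid a [ts_grid()].
#' @param f_low,f_high band edges in Hz; must satisfy
#'   `f_low < f_high < 1/(2 * tr_seconds)`.
#' @param method `"butterworth"` (default) or `"fft"`.
#' @param order Butterworth order before the forward-backward pass.
#' @return A [ts_grid()] with identical mask, TR and pixel size.
#' @export
bandpass <- function(grid, f_low = 0.009, f_high = 0.08,
                     method = c("butterworth", "fft"), order = 4L) {
  method <- match.arg(method)
  stopifnot(inherits(grid, "ts_grid"))
  nyq <- 1 / (2 * grid$tr_seconds)
  if (!(f_low < f_high)) stop("`f_low` must be below `f_high`")
  if (f_high >= nyq)
    stop(sprintf("`f_high` (%g Hz) must be below the Nyquist frequency %g Hz (TR = %g s)",
                 f_high, nyq, grid$tr_seconds))
  if (f_low <= 0) stop("`f_low` must be positive")
  s <- grid_series(grid)
  s <- s - rowMeans(s)
  if (method == "butterworth") {
    bf <- signal::butter(order, c(f_low, f_high) / nyq, type = "pass")
    out <- t(apply(s, 1L, function(x) signal::filtfilt(bf, x)))
    # filtfilt edge transients leave a small DC residue; DC is outside the
    # passband, so remove it exactly
    out <- out - rowMeans(out)
  } else {
    fs <- 1 / grid$tr_seconds
    out <- t(apply(s, 1L, fft_bandlimit, fs = fs, f_low = f_low, f_high = f_high))
  }
  grid_replace_series(grid, out)
}

# ideal band-pass by zeroing FFT bins outside [f_low, f_high] (two-sided)
fft_bandlimit <- function(x, fs, f_low, f_high) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)              # fold to [0, fs/2]
  keep <- f >= f_low & f <= f_high
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Regress nuisance signals out of every pixel series
#'
#' Removes, by ordinary least squares, the span of an intercept plus the
#' supplied nuisance regressors (typically head-motion parameters and the
#' mean whole-brain, ventricular and white-matter signals) from each masked
#' pixel's time series, replacing the series by the residuals. Residuals are
#' exactly orthogonal to every regressor.
#'
#' @param grid a [ts_grid()].
#' @param regressors numeric matrix with `T` rows, one column per nuisance
#'   signal. Column names, if present, are used in error messages.
#' @param filter_regressors if `TRUE`, band-pass the regressors with the
#'   same default band as [bandpass()] before fitting (the two linear
#'   operations commute for band-limited regressors, so this mainly matters
#'   when regressors carry out-of-band power).
#' @return A [ts_grid()] of residual series; mask, TR and pixel size are
#'   preserved.
#' @export
nuisance_regress <- function(grid, regressors, filter_regressors = FALSE) {
  stopifnot(inherits(grid, "ts_grid"))
  t_len <- dim(grid$data)[3]
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != t_len)
    stop("`regressors` must have one row per time point (T = ", t_len, ")")
  if (isTRUE(filter_regressors)) {
    fs <- 1 / grid$tr_seconds
    regressors <- apply(regressors, 2L, fft_bandlimit, fs = fs,
                        f_low = 0.009, f_high = 0.08)
  }
  X <- cbind(`(intercept)` = 1, regressors)
  if (ncol(X) > t_len - 2L)
    stop("design has more columns than T - 2; too many regressors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    nm <- colnames(X)
    nm <- if (is.null(nm)) paste0("column ", bad) else nm[bad]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(nm, collapse = ", "))
  }
  s <- grid_series(grid)                 # n x T
  res <- t(qr.resid(qrX, t(s)))          # residualize all pixels at once
  grid_replace_series(grid, res)
}
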