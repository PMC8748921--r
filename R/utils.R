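#' @keywords internal
"_PACKAGE"

#' Trapezoidal integral
#' @param x,y numeric vectors of equal length
#' @return scalar integral of y over x
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Advance a sampled series by an integer number of samples
#'
#' Positive `k` advances the series (value at index i becomes the value that
#' was at i + k); the trailing edge is held at the last value so the length
#' is unchanged.
#' @keywords internal
advance_series <- function(x, k) {
  n <- length(x)
  k <- as.integer(round(k))
  if (k == 0L) return(x)
  if (abs(k) >= n) stop("shift exceeds record length")
  if (k > 0L) c(x[(k + 1L):n], rep(x[n], k)) else c(rep(x[1L], -k), x[1L:(n + k)])
}

#' Low-pass smooth a channel (shared smoothing step for derivatives)
#' @param x channel samples
#' @param fs sampling rate (Hz)
#' @param cutoff_hz low-pass corner; values at or above Nyquist disable smoothing
#' @keywords internal
smooth_channel <- function(x, fs, cutoff_hz = 125) {
  if (!is.finite(cutoff_hz) || cutoff_hz >= fs / 2) return(x)
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Central-difference derivative after the shared smoothing step
#' @keywords internal
derive_channel <- function(x, fs, cutoff_hz = 125) {
  xs <- smooth_channel(x, fs, cutoff_hz)
  n <- length(xs)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) * fs / 2
  d[1] <- (xs[2] - xs[1]) * fs
  d[n] <- (xs[n] - xs[n - 1]) * fs
  d
}

#' Variance accounted for
#'
#' VAF = 1 - var(observed - predicted) / var(observed). Equals 1 for a
#' perfect prediction and 0 for the constant mean predictor.
#'
#' @param observed,predicted equal-length numeric vectors
#' @return scalar VAF (at most 1; can be negative for predictions worse
#'   than the mean)
#' @export
vaf <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("observed and predicted lengths differ")
  vo <- stats::var(observed)
  if (!is.finite(vo) || vo == 0) stop("zero-variance observed signal")
  1 - stats::var(observed - predicted) / vo
}
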