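#' Spectral power summary of a motion channel
#'
#' Averaged modified periodograms (Welch): Hamming-tapered, mean-removed
#' segments with 50% overlap. The one-sided PSD integrates to the channel
#' variance (Parseval, within taper tolerance). The cumulative spectrum is
#' normalized over the analysis band and its area is reported; spectra with
#' relatively more high-frequency power have smaller area under the
#' cumulative curve.
#'
#' @param x channel samples (uniformly sampled)
#' @param fs sampling rate, Hz
#' @param window_s segment length, s
#' @param overlap fractional overlap between segments
#' @param band analysis band (Hz) for the cumulative curve
#' @return `spectral_summary`: frequencies, psd (units^2/Hz),
#'   cumulative_normalized, auc_cumulative, band
#' @export
spectral_power <- function(x, fs, window_s = 2, overlap = 0.5, band = c(0, 15)) {
  nw <- round(window_s * fs)
  n <- length(x)
  if (n < nw) stop("record shorter than one analysis window")
  step <- max(1, round(nw * (1 - overlap)))
  starts <- seq(1, n - nw + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nw) / (nw + 1))
  u <- sum(w^2)
  nf <- floor(nw / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    p <- p[1:nf]
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  psd <- acc / length(starts)
  freqs <- (0:(nf - 1)) * fs / nw
  sel <- freqs >= band[1] & freqs <= band[2]
  cum <- cumsum(psd[sel])
  cum <- cum / cum[length(cum)]
  structure(list(frequencies = freqs, psd = psd,
                 cumulative_normalized = cum,
                 cumulative_frequencies = freqs[sel],
                 auc_cumulative = trapz(freqs[sel], cum),
                 band = band),
            class = "spectral_summary")
}

#' Fraction of samples beyond k reference SDs
#'
#' Fraction of test-channel samples with |x - mean(ref)| > k * SD(ref);
#' with a walking-matched passive reference and k = 1.5 this is the
#' amplitude-tail statistic used to compare locomotion against passive
#' stimulation.
#' @param test,reference numeric channels
#' @param k SD multiple
#' @export
tail_fraction <- function(test, reference, k = 1.5) {
  s <- stats::sd(reference)
  if (!is.finite(s) || s == 0) stop("zero reference SD")
  mean(abs(test - mean(reference)) > k * s)
}

#' Amplitude-distribution summary (SD and kurtosis)
#'
#' Kurtosis uses the Pearson (non-excess) convention: 3 for a Gaussian.
#' @param x numeric channel (at least 4 samples)
#' @return list(sd, kurtosis)
#' @export
distribution_summary <- function(x) {
  if (length(x) < 4) stop("need at least 4 samples")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("kurtosis undefined for a constant channel")
  list(sd = stats::sd(x), kurtosis = mean((x - mean(x))^4) / m2^2)
}

#' Mean head orientation (pitch) from gravity-dominated acceleration
#'
#' Low-pass filters the acceleration axes to isolate the gravity component
#' and averages the pitch angle of the resulting vector. With a single
#' (fore-aft) axis the dorsoventral axis is taken as carrying 1 g.
#' @param acc_fore fore-aft linear acceleration, g
#' @param acc_vert dorsoventral linear acceleration, g (default: constant
#'   1 g gravity convention)
#' @param fs sampling rate, Hz
#' @param cutoff_hz gravity-extraction low-pass corner
#' @return mean pitch angle, deg
#' @export
mean_orientation <- function(acc_fore, acc_vert = NULL, fs, cutoff_hz = 0.5) {
  if (is.null(acc_vert)) acc_vert <- rep(1, length(acc_fore))
  lp <- function(x) {
    if (stats::sd(x) == 0 || cutoff_hz >= fs / 2) return(x)
    bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
    as.numeric(signal::filtfilt(bf, x))
  }
  gf <- lp(acc_fore)
  gv <- lp(acc_vert)
  mag <- sqrt(gf^2 + gv^2)
  if (mean(mag) < 1e-9) stop("zero gravity-component magnitude")
  mean(atan2(gf, gv)) * 180 / pi
}
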