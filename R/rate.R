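#' Continuous firing-rate trace container
#' @param t uniform time grid, s
#' @param rate non-negative firing rate, sp/s
#' @export
rate_trace <- function(t, rate) {
  stopifnot(length(t) == length(rate))
  structure(list(t = t, rate = rate, sample_rate = round(1 / stats::median(diff(t)))),
            class = "rate_trace")
}

#' Estimate the time-dependent firing rate by Kaiser-window low-pass filtering
#'
#' The spike train is binned into counts on the stimulus grid and convolved
#' with a unit-DC-gain Kaiser-window FIR low-pass filter. The default
#' 25 Hz cutoff sits comfortably above locomotor head-motion content at
#' 1 kHz sampling; the Kaiser shape parameter is set for the requested
#' stop-band attenuation. Small negative filter ringing is clipped at zero.
#'
#' @param spike_times sorted spike times, s
#' @param t uniform analysis grid, s (typically the stimulus grid)
#' @param cutoff_hz low-pass corner, Hz
#' @param stopband_db stop-band attenuation target, dB (sets the Kaiser beta
#'   and filter length)
#' @param transition_hz transition-band width, Hz
#' @param clip_negative clip filter ringing at zero (the default keeps the
#'   rate non-negative; disable to obtain the exactly linear estimator)
#' @return a [rate_trace()] on `t`; the integral of the rate approximates
#'   the spike count
#' @export
estimate_firing_rate <- function(spike_times, t, cutoff_hz = 25,
                                 stopband_db = 60, transition_hz = 10,
                                 clip_negative = TRUE) {
  if (length(spike_times) && is.unsorted(spike_times)) stop("spike times must be sorted")
  n <- length(t)
  dt <- t[2] - t[1]
  fs <- 1 / dt
  if (length(spike_times) &&
      (min(spike_times) < t[1] - dt / 2 || max(spike_times) > t[n] + dt / 2)) {
    stop("spikes outside the grid span")
  }
  counts <- tabulate(findInterval(spike_times, t - dt / 2, all.inside = TRUE), nbins = n)
  if (!length(spike_times)) return(rate_trace(t, numeric(n)))
  beta <- 0.1102 * (stopband_db - 8.7)
  ntaps <- ceiling((stopband_db - 8) / (2.285 * 2 * pi * transition_hz / fs))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps - 1, cutoff_hz / (fs / 2), type = "low",
                    window = signal::kaiser(ntaps, beta))
  h <- h / sum(h)
  half <- (ntaps - 1) / 2
  y <- stats::convolve(c(counts, numeric(ntaps)), rev(h), type = "open")
  rate <- y[(half + 1):(half + n)] / dt
  if (clip_negative) rate <- pmax(rate, 0)
  rate_trace(t, rate)
}

#' Interspike-interval regularity metrics and CV* classification
#'
#' Computes the ISI coefficient of variation and its normalized form CV*,
#' the CV mapped to a standard mean ISI (15 ms) along constant-shape
#' contours of a calibration table built from the package's own
#' gamma-renewal simulations (an explicit, reproducible approximation of
#' the classical normalization curves). Afferents with CV* at or above
#' 0.15 are classified irregular.
#'
#' @param spike_times resting (stimulus-free) spike times, s
#' @param min_isis minimum number of ISIs required
#' @param standard_isi_ms mean ISI to which CV is normalized
#' @param calibration calibration table (data.frame kappa, mean_isi_ms, cv);
#'   defaults to the table shipped with the package
#' @param cutoff CV* classification cutoff (ties classified irregular)
#' @return list of class `regularity_metrics`: mean_isi (s), cv, cv_star,
#'   class_label
#' @export
interspike_regularity <- function(spike_times, min_isis = 500,
                                  standard_isi_ms = 15,
                                  calibration = NULL, cutoff = 0.15) {
  isi <- diff(spike_times)
  if (length(isi) < min_isis) {
    stop("need at least ", min_isis, " interspike intervals from stimulus-free epochs")
  }
  if (any(isi <= 0)) stop("non-positive interspike intervals")
  mean_isi <- mean(isi)
  cv <- stats::sd(isi) / mean_isi
  cv_star <- normalize_cv(cv, mean_isi * 1000, standard_isi_ms, calibration)
  structure(list(mean_isi = mean_isi, cv = cv, cv_star = cv_star,
                 class_label = if (cv_star >= cutoff) "irregular" else "regular"),
            class = "regularity_metrics")
}

#' @keywords internal
load_cv_calibration <- function() {
  path <- system.file("extdata", "cv_star_calibration.csv", package = "vestaff")
  if (!nzchar(path)) stop("calibration table not found")
  utils::read.csv(path)
}

#' Map an observed (cv, mean ISI) pair to the standard mean ISI
#'
#' Interpolates the calibration table: the cv-vs-mean-ISI curve of each
#' renewal shape is evaluated at the observed mean ISI, the observed cv is
#' located among those curves (interpolating across log-shape), and the
#' matched curve is read out at the standard mean ISI. Monotone in cv by
#' construction. Degenerate cv = 0 maps to 0.
#' @keywords internal
normalize_cv <- function(cv, mean_isi_ms, standard_isi_ms = 15, calibration = NULL) {
  if (cv <= 0) return(0)
  if (is.null(calibration)) calibration <- load_cv_calibration()
  kappas <- sort(unique(calibration$kappa), decreasing = TRUE)  # cv increasing
  cv_at_obs <- cv_at_std <- numeric(length(kappas))
  for (i in seq_along(kappas)) {
    rows <- calibration[calibration$kappa == kappas[i], ]
    cv_at_obs[i] <- stats::approx(rows$mean_isi_ms, rows$cv, xout = mean_isi_ms, rule = 2)$y
    cv_at_std[i] <- stats::approx(rows$mean_isi_ms, rows$cv, xout = standard_isi_ms, rule = 2)$y
  }
  if (cv < min(cv_at_obs)) {
    # below the most regular tabulated shape: scale proportionally toward 0
    i <- which.min(cv_at_obs)
    return(cv * cv_at_std[i] / cv_at_obs[i])
  }
  if (cv > max(cv_at_obs)) {
    i <- which.max(cv_at_obs)
    return(cv * cv_at_std[i] / cv_at_obs[i])
  }
  stats::approx(cv_at_obs, cv_at_std, xout = cv)$y
}

#' Build the CV* calibration table from gamma-renewal simulations
#'
#' Simulates resting gamma-renewal spike trains across a grid of shapes and
#' mean ISIs and tabulates the observed ISI CV. The shipped
#' `inst/extdata/cv_star_calibration.csv` is the output of this function at
#' its defaults.
#' @param kappas renewal shape grid
#' @param mean_isis_ms mean ISI grid, ms
#' @param n_isi ISIs per cell
#' @param seed RNG seed
#' @return data.frame(kappa, mean_isi_ms, cv)
#' @export
cv_star_calibration <- function(kappas = c(1, 2, 4, 9, 16, 25, 44, 64, 100, 200),
                                mean_isis_ms = c(5, 10, 15, 20, 30, 50),
                                n_isi = 50000, seed = 42) {
  set.seed(seed)
  grid <- expand.grid(kappa = kappas, mean_isi_ms = mean_isis_ms)
  grid$cv <- vapply(seq_len(nrow(grid)), function(i) {
    isi <- stats::rgamma(n_isi, shape = grid$kappa[i],
                         scale = grid$mean_isi_ms[i] / 1000 / grid$kappa[i])
    stats::sd(isi) / mean(isi)
  }, numeric(1))
  grid
}

#' Cycle-averaged response statistics
#'
#' Splits the rate trace into complete cycles of the stimulation frequency
#' and reports the average peak-to-peak discharge modulation across cycles
#' together with the time-averaged firing rate.
#'
#' @param rate a [rate_trace()]
#' @param frequency fundamental stimulation frequency, Hz (ignored when
#'   `cycle_markers` given)
#' @param cycle_markers optional cycle onset times, s
#' @param folded if TRUE, cycles are averaged into one waveform first and the
#'   modulation is its peak-to-peak depth (suppresses spiking noise); the
#'   default takes the mean of per-cycle peak-to-peak depths
#' @param resting_rate optional resting discharge to carry in the result
#' @return list of class `cycle_stats`: mean_rate, modulation (sp/s),
#'   resting_discharge
#' @export
cycle_modulation <- function(rate, frequency = NULL, cycle_markers = NULL,
                             folded = FALSE, resting_rate = NA_real_) {
  if (!length(rate$rate)) stop("empty rate trace")
  if (is.null(cycle_markers)) {
    if (is.null(frequency) || frequency <= 0) stop("need a positive frequency or cycle markers")
    per <- round(rate$sample_rate / frequency)
    ncyc <- floor(length(rate$rate) / per)
    if (ncyc < 1) stop("no complete cycle in the record")
    starts <- (seq_len(ncyc) - 1) * per + 1
    ends <- starts + per - 1
  } else {
    idx <- findInterval(cycle_markers, rate$t)
    if (length(idx) < 2) stop("no complete cycle in the record")
    starts <- idx[-length(idx)]
    ends <- idx[-1] - 1
    ncyc <- length(starts)
  }
  if (folded && is.null(cycle_markers)) {
    per <- ends[1] - starts[1] + 1
    waveform <- rowMeans(vapply(seq_len(ncyc), function(i) {
      rate$rate[starts[i]:ends[i]]
    }, numeric(per)))
    modulation <- max(waveform) - min(waveform)
  } else {
    ptp <- vapply(seq_len(ncyc), function(i) {
      seg <- rate$rate[starts[i]:ends[i]]
      max(seg) - min(seg)
    }, numeric(1))
    modulation <- mean(ptp)
  }
  used <- rate$rate[starts[1]:ends[ncyc]]
  structure(list(mean_rate = mean(used), modulation = modulation,
                 resting_discharge = resting_rate, n_cycles = ncyc),
            class = "cycle_stats")
}

#' Probability of (near-)zero firing rate
#'
#' Fraction of samples at or below `epsilon` sp/s; the default epsilon
#' absorbs low-pass filter ringing around true silence.
#' @param rate a [rate_trace()] (or numeric rate vector)
#' @param epsilon threshold, sp/s
#' @export
zero_rate_probability <- function(rate, epsilon = 0.5) {
  x <- if (inherits(rate, "rate_trace")) rate$rate else rate
  if (!length(x)) stop("empty rate trace")
  if (epsilon < 0) stop("epsilon must be non-negative")
  mean(x <= epsilon)
}
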