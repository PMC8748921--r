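#' Head-motion conditions known to the simulator
#' @export
STIMULUS_CONDITIONS <- c(
  "passive_sinusoid_translation", "passive_sinusoid_pitch",
  "passive_low", "passive_high", "walking", "running"
)

#' Default stimulus-generator parameters
#'
#' The naturalistic conditions are band-limited processes whose marginal
#' amplitude distributions are calibrated, in closed form, to target
#' fractions of samples beyond +/- 1.5 SD of the walking-matched passive
#' reference. Walking and the walking-matched passive condition
#' (`passive_low`) share the configured SD and spectral shape; running and
#' its matched passive condition (`passive_high`) have the same SD ratio
#' and a heavier-tailed amplitude distribution realised as a two-component
#' Gaussian scale mixture.
#'
#' @param sample_rate sampling rate, Hz
#' @param accel_sd_walk SD of net linear acceleration in the walking /
#'   walking-matched passive pair, in g
#' @param rot_sd_walk SD of pitch velocity in the walking pair, deg/s
#' @param sd_ratio_run running-to-walking SD ratio of net linear acceleration
#' @param sd_ratio_run_rot running-to-walking SD ratio of pitch velocity (the
#'   rotational power elevation during running is milder than the linear one)
#' @param corner_hz_walk,corner_hz_run spectral corner frequency of the
#'   band-limited process (power falls as \eqn{1/(1+(f/f_c)^{2q})})
#' @param spectral_order q, the roll-off order of the band-limit
#' @param tail_target_accel named fractions (passive, walking, running) of
#'   net-acceleration samples expected beyond 1.5 SD of the walking-matched
#'   passive reference
#' @param tail_target_rot same for the pitch-velocity channel
#' @param mix_p mixing weight of the wide component in the running
#'   acceleration scale mixture
#' @param envelope_hz corner of the slow envelope that switches the running
#'   mixture components (burst time scale)
#' @param k_ref reference tail multiple (1.5 SD bands)
#' @param sin_freq_hz,sin_amp_g,sin_amp_dps sinusoidal passive stimulation:
#'   frequency, linear-acceleration amplitude (g) and pitch-velocity
#'   amplitude (deg/s)
#' @param smooth_hz shared low-pass applied before differentiating channels
#' @return list of class `stimulus_params`
#' @export
stimulus_params <- function(sample_rate = 1000,
                            accel_sd_walk = 0.12,
                            rot_sd_walk = 15,
                            sd_ratio_run = 2,
                            sd_ratio_run_rot = 1.1,
                            corner_hz_walk = 4,
                            corner_hz_run = 5.5,
                            spectral_order = 4,
                            tail_target_accel = c(passive = 0.03, walking = 0.05, running = 0.15),
                            tail_target_rot = c(passive = 0.03, walking = 0.02, running = 0.04),
                            mix_p = 0.2,
                            envelope_hz = 1,
                            k_ref = 1.5,
                            sin_freq_hz = 1,
                            sin_amp_g = 0.2,
                            sin_amp_dps = 40,
                            smooth_hz = 125) {
  p <- list(
    sample_rate = sample_rate, accel_sd_walk = accel_sd_walk,
    rot_sd_walk = rot_sd_walk, sd_ratio_run = sd_ratio_run,
    sd_ratio_run_rot = sd_ratio_run_rot,
    corner_hz_walk = corner_hz_walk, corner_hz_run = corner_hz_run,
    spectral_order = spectral_order,
    tail_target_accel = tail_target_accel, tail_target_rot = tail_target_rot,
    mix_p = mix_p, envelope_hz = envelope_hz, k_ref = k_ref,
    sin_freq_hz = sin_freq_hz, sin_amp_g = sin_amp_g, sin_amp_dps = sin_amp_dps,
    smooth_hz = smooth_hz
  )
  class(p) <- "stimulus_params"
  p
}

## ---- amplitude-distribution families ------------------------------------

#' Tail probability of the squashed-Gaussian amplitude family
#'
#' The light-tailed family is y = tanh(lambda * z) / lambda with z standard
#' normal; lambda -> 0 recovers the Gaussian, large lambda approaches a
#' bounded two-point distribution. Returns P(|Y| > k * SD(Y)), evaluated
#' analytically (the SD by quadrature, the tail through the monotone
#' transform).
#'
#' @param lambda squash parameter (> 0 strength; 0 allowed, meaning Gaussian)
#' @param k tail multiple in units of the family's own SD
#' @return tail probability in [0, 1]
#' @export
squash_tail_probability <- function(lambda, k) {
  if (lambda <= 1e-8) return(2 * stats::pnorm(-k))
  s <- squash_sd(lambda)
  thr <- k * s
  if (lambda * thr >= 1) return(0)
  2 * stats::pnorm(atanh(lambda * thr) / lambda, lower.tail = FALSE)
}

#' @keywords internal
squash_sd <- function(lambda) {
  if (lambda <= 1e-8) return(1)
  f <- function(z) (tanh(lambda * z) / lambda)^2 * stats::dnorm(z)
  sqrt(2 * stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

#' Calibrate the squash parameter to a target tail fraction
#' @param target desired P(|Y| > k SD(Y))
#' @param k tail multiple (own-SD units)
#' @return lambda
#' @keywords internal
calibrate_squash <- function(target, k) {
  gauss <- 2 * stats::pnorm(-k)
  if (target >= gauss) {
    if (abs(target - gauss) < 1e-6) return(0)
    stop("tail target exceeds the Gaussian tail; unachievable for the squash family")
  }
  f <- function(loglam) squash_tail_probability(exp(loglam), k) - target
  stats::uniroot(f, c(log(1e-4), log(50)), tol = 1e-12)$root |> exp()
}

#' Tail probability of a two-component Gaussian scale mixture
#'
#' P(|X| > c) for X ~ (1-p) N(0, sigma1^2) + p N(0, sigma2^2).
#' @export
mixture_tail_probability <- function(sigma1, sigma2, p, c) {
  (1 - p) * 2 * stats::pnorm(-c / sigma1) + p * 2 * stats::pnorm(-c / sigma2)
}

#' Calibrate the running-condition scale mixture
#'
#' Solves for the narrow-component SD (wide component then fixed by the
#' total-variance constraint) so that the mixture places `target` mass
#' beyond `k` reference SDs, where the reference SD is 1 and the mixture
#' total SD is `ratio`.
#' @keywords internal
calibrate_mixture <- function(target, p, ratio, k) {
  upper <- ratio / sqrt(1 - p) - 1e-6
  f <- function(s1) {
    s2sq <- (ratio^2 - (1 - p) * s1^2) / p
    mixture_tail_probability(s1, sqrt(s2sq), p, k) - target
  }
  lo <- 0.2
  if (f(lo) * f(upper) > 0) {
    stop("tail-fraction target unachievable for the configured mixture family")
  }
  s1 <- stats::uniroot(f, c(lo, upper), tol = 1e-12)$root
  s2 <- sqrt((ratio^2 - (1 - p) * s1^2) / p)
  c(sigma1 = s1, sigma2 = s2)
}

#' Analytic amplitude calibration implied by a parameter set
#'
#' Computes, before any sampling, the squash/mixture parameters for every
#' naturalistic condition and the analytic tail probabilities they imply at
#' the configured reference band. Used both by the generator and by the
#' calibration invariance tests.
#'
#' @param params a [stimulus_params()] list
#' @return nested list with elements `accel` and `rot`, each holding the
#'   per-condition family parameters and analytic tail probabilities
#' @export
stimulus_tail_calibration <- function(params = stimulus_params()) {
  k <- params$k_ref
  ratio <- params$sd_ratio_run
  ta <- params$tail_target_accel
  tr <- params$tail_target_rot
  lam_acc_pas <- calibrate_squash(ta[["passive"]], k)
  lam_acc_walk <- calibrate_squash(ta[["walking"]], k)
  mix <- calibrate_mixture(ta[["running"]], params$mix_p, ratio, k)
  lam_rot_pas <- calibrate_squash(tr[["passive"]], k)
  lam_rot_walk <- calibrate_squash(tr[["walking"]], k)
  lam_rot_run <- calibrate_squash(tr[["running"]], k / params$sd_ratio_run_rot)
  list(
    accel = list(
      passive = list(lambda = lam_acc_pas,
                     tail = squash_tail_probability(lam_acc_pas, k)),
      walking = list(lambda = lam_acc_walk,
                     tail = squash_tail_probability(lam_acc_walk, k)),
      running = list(sigma1 = mix[["sigma1"]], sigma2 = mix[["sigma2"]],
                     p = params$mix_p,
                     tail = mixture_tail_probability(mix[["sigma1"]], mix[["sigma2"]],
                                                    params$mix_p, k))
    ),
    rot = list(
      passive = list(lambda = lam_rot_pas,
                     tail = squash_tail_probability(lam_rot_pas, k)),
      walking = list(lambda = lam_rot_walk,
                     tail = squash_tail_probability(lam_rot_walk, k)),
      running = list(lambda = lam_rot_run,
                     tail = squash_tail_probability(lam_rot_run, k / params$sd_ratio_run_rot))
    )
  )
}

## ---- band-limited process -----------------------------------------------

#' Band-limited standard Gaussian series (unit sample SD, zero sample mean)
#' @keywords internal
band_limited_gaussian <- function(n, fs, corner_hz, order = 2) {
  w <- stats::rnorm(n)
  if (corner_hz >= fs / 2) {
    z <- w
  } else {
    f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
    h <- 1 / sqrt(1 + (abs(f) / corner_hz)^(2 * order))
    z <- Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / n
  }
  as.numeric(scale(z))
}

## ---- generator ----------------------------------------------------------

#' Generate a condition-specific head-motion stimulus
#'
#' Sinusoidal conditions are exact sinusoids at the configured frequency and
#' amplitude. Naturalistic conditions are band-limited processes with
#' calibrated marginal amplitude distributions: walking and the
#' walking-matched passive pitch (`passive_low`) are light-tailed
#' (squashed-Gaussian) processes of equal SD; running (and its matched
#' passive condition `passive_high`) has a larger SD, relatively more
#' high-frequency power, and a heavy-tailed acceleration marginal realised
#' as a two-component Gaussian scale mixture switched by a slow envelope.
#'
#' @param condition one of [STIMULUS_CONDITIONS]
#' @param duration record length, s
#' @param params a [stimulus_params()] list
#' @param seed RNG seed (required for the stochastic conditions)
#' @return a `stimulus_trace`
#' @export
generate_stimulus <- function(condition, duration, params = stimulus_params(), seed = NULL) {
  condition <- match.arg(condition, STIMULUS_CONDITIONS)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  fs <- params$sample_rate
  n <- round(duration * fs)
  t <- seq(0, by = 1 / fs, length.out = n)

  if (condition %in% c("passive_sinusoid_translation", "passive_sinusoid_pitch")) {
    ph <- 2 * pi * params$sin_freq_hz * t
    if (condition == "passive_sinusoid_translation") {
      vel <- rep(0, n)
      acc <- params$sin_amp_g * sin(ph)
    } else {
      vel <- params$sin_amp_dps * sin(ph)
      acc <- params$sin_amp_g * sin(ph)
    }
    return(stimulus_trace(t, vel, acc, condition, fs, params$smooth_hz))
  }

  if (is.null(seed)) stop("a seed is required for stochastic conditions")
  set.seed(as.integer(seed))
  cal <- stimulus_tail_calibration(params)
  high <- condition %in% c("running", "passive_high")
  corner <- if (high) params$corner_hz_run else params$corner_hz_walk
  q <- params$spectral_order

  squash_scale <- function(z, lambda, target_sd) {
    if (target_sd == 0) return(rep(0, length(z)))
    y <- if (lambda <= 1e-8) z else tanh(lambda * z) / lambda
    # exact sample-SD scaling keeps tail thresholds stable across records
    y * target_sd / stats::sd(y)
  }

  if (high) {
    rot_sd <- params$rot_sd_walk * params$sd_ratio_run_rot
    vel <- squash_scale(band_limited_gaussian(n, fs, corner, q),
                        cal$rot$running$lambda, rot_sd)
    if (params$accel_sd_walk == 0) {
      acc <- rep(0, n)
    } else {
      z <- band_limited_gaussian(n, fs, corner, q)
      u <- band_limited_gaussian(n, fs, params$envelope_hz, q)
      wide <- stats::pnorm(u) > 1 - params$mix_p
      comp_sd <- ifelse(wide, cal$accel$running$sigma2, cal$accel$running$sigma1)
      acc <- z * comp_sd * params$accel_sd_walk
    }
  } else {
    key <- if (condition == "walking") "walking" else "passive"
    vel <- squash_scale(band_limited_gaussian(n, fs, corner, q),
                        cal$rot[[key]]$lambda, params$rot_sd_walk)
    acc <- squash_scale(band_limited_gaussian(n, fs, corner, q),
                        cal$accel[[key]]$lambda, params$accel_sd_walk)
  }
  stimulus_trace(t, vel, acc, condition, fs, params$smooth_hz)
}

#' Construct a stimulus trace with derived derivative channels
#'
#' @param t uniform time grid, s
#' @param pitch_velocity pitch angular velocity, deg/s
#' @param linear_acceleration net gravito-inertial acceleration, g
#' @param condition condition label from [STIMULUS_CONDITIONS]
#' @param sample_rate Hz
#' @param smooth_hz shared low-pass corner applied before differencing
#' @return list of class `stimulus_trace` with channels `t`,
#'   `pitch_velocity`, `pitch_acceleration` (deg/s^2), `linear_acceleration`,
#'   `jerk` (g/s)
#' @export
stimulus_trace <- function(t, pitch_velocity, linear_acceleration, condition,
                           sample_rate, smooth_hz = 125) {
  condition <- match.arg(condition, STIMULUS_CONDITIONS)
  n <- length(t)
  stopifnot(length(pitch_velocity) == n, length(linear_acceleration) == n)
  dt <- diff(t)
  if (n > 1 && (any(dt <= 0) || diff(range(dt)) > 1e-9 / sample_rate * n)) {
    stop("time grid must be strictly increasing and uniform")
  }
  out <- list(
    t = t,
    pitch_velocity = pitch_velocity,
    pitch_acceleration = derive_channel(pitch_velocity, sample_rate, smooth_hz),
    linear_acceleration = linear_acceleration,
    jerk = derive_channel(linear_acceleration, sample_rate, smooth_hz),
    condition = condition,
    sample_rate = sample_rate,
    smooth_hz = smooth_hz
  )
  class(out) <- "stimulus_trace"
  out
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf(
    "stimulus_trace: %s, %.1f s @ %g Hz\n  pitch velocity SD %.2f deg/s, linear acceleration SD %.4f g\n",
    x$condition, length(x$t) / x$sample_rate, x$sample_rate,
    stats::sd(x$pitch_velocity), stats::sd(x$linear_acceleration)
  ))
  invisible(x)
}

## ---- file interfaces ----------------------------------------------------

#' Write / read a stimulus trace as delimited text
#'
#' Columns `time_s`, `pitch_velocity_dps`, `linear_accel_g`; header row
#' mandatory. Derived channels are recomputed on read.
#' @param x a `stimulus_trace`
#' @param path file path
#' @export
write_stimulus_csv <- function(x, path) {
  utils::write.csv(
    data.frame(time_s = x$t, pitch_velocity_dps = x$pitch_velocity,
               linear_accel_g = x$linear_acceleration),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @param condition condition label to attach on read
#' @param smooth_hz smoothing corner for recomputed derivative channels
#' @export
read_stimulus_csv <- function(path, condition = "passive_low", smooth_hz = 125) {
  d <- utils::read.csv(path)
  need <- c("time_s", "pitch_velocity_dps", "linear_accel_g")
  if (!all(need %in% names(d))) stop("stimulus file must have columns ", paste(need, collapse = ", "))
  fs <- 1 / stats::median(diff(d$time_s))
  stimulus_trace(d$time_s, d$pitch_velocity_dps, d$linear_accel_g,
                 condition, round(fs), smooth_hz)
}
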