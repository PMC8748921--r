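#' Erf-sigmoid static nonlinearity
#'
#' Tsig(x) = (c3/2) * (1 + erf((x - c2) / sqrt(2 c1))), written here through
#' the normal CDF (identical function): c3 * pnorm((x - c2) / sqrt(c1)).
#' c1 is a width (variance-like, input units squared), c2 the inflection
#' location and c3 the upper asymptote (sp/s). Tsig(c2) = c3/2 and the
#' asymptotes are 0 and c3.
#'
#' @param x input (linear drive, sp/s)
#' @param c1,c2,c3 sigmoid parameters (or pass a `sigmoid_params` as `c1`)
#' @return firing rate, sp/s
#' @export
tsig <- function(x, c1, c2 = NULL, c3 = NULL) {
  if (inherits(c1, "sigmoid_params")) {
    p <- c1; c1 <- p$c1; c2 <- p$c2; c3 <- p$c3
  }
  c3 * stats::pnorm((x - c2) / sqrt(c1))
}

#' Local slope of the erf sigmoid
#' @inheritParams tsig
#' @export
tsig_slope <- function(x, c1, c2 = NULL, c3 = NULL) {
  if (inherits(c1, "sigmoid_params")) {
    p <- c1; c1 <- p$c1; c2 <- p$c2; c3 <- p$c3
  }
  c3 * stats::dnorm((x - c2) / sqrt(c1)) / sqrt(c1)
}

#' Sigmoid parameter container
#' @param c1 width parameter, (input units)^2; must be > 0
#' @param c2 inflection location, input units
#' @param c3 upper asymptote, sp/s; must be > 0
#' @export
sigmoid_params <- function(c1, c2, c3) {
  if (!is.finite(c1) || c1 <= 0) stop("c1 must be positive")
  if (!is.finite(c3) || c3 <= 0) stop("c3 must be positive")
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "sigmoid_params")
}

#' Sigmoid with a prescribed resting point and slope
#'
#' Builds an erf sigmoid that passes through (r0, r0) with local slope
#' `slope` there, with rest placed at the inflection (c2 = r0, c3 = 2 r0).
#' Convenient ground truth for simulated afferents: at rest the cell fires
#' at its resting discharge and the nonlinearity is locally a unit-gain
#' wire.
#' @param r0 resting discharge, sp/s
#' @param slope local gain at the resting point
#' @export
resting_sigmoid <- function(r0, slope = 1) {
  c3 <- 2 * r0
  c1 <- (c3 / (slope * sqrt(2 * pi)))^2
  sigmoid_params(c1, r0, c3)
}

#' Ground-truth description of a synthetic afferent
#'
#' Canal afferents are driven by pitch velocity and acceleration
#' (coefficients `sv`, `sa`); otolith afferents by net linear acceleration
#' and jerk (`sa`, `sj`). The bias of the linear drive is the resting
#' discharge `r0`. The drive is passed through either hard rectification at
#' zero ("linear-rectified") or an erf sigmoid, and spikes are drawn from an
#' inhomogeneous gamma-renewal process with shape `kappa` (resting ISI
#' CV ~= 1/sqrt(kappa)).
#'
#' @param organ "canal" or "otolith"
#' @param regularity "regular" or "irregular"
#' @param r0 resting discharge, sp/s (> 0)
#' @param sv canal velocity coefficient, (sp/s)/(deg/s)
#' @param sa canal acceleration coefficient (sp/s)/(deg/s^2), or otolith
#'   acceleration coefficient (sp/s)/g
#' @param sj otolith jerk coefficient, (sp/s)/(g/s)
#' @param lead response lead, s (positive: firing precedes motion; applied
#'   by advancing the stimulus)
#' @param nonlinearity "linear-rectified" or "sigmoid"
#' @param sigmoid a [sigmoid_params()] (required when nonlinearity is
#'   "sigmoid")
#' @param kappa gamma-renewal shape, >= 1
#' @export
afferent_truth <- function(organ = c("canal", "otolith"),
                           regularity = c("regular", "irregular"),
                           r0, sv = NULL, sa = NULL, sj = NULL,
                           lead = 0,
                           nonlinearity = c("linear-rectified", "sigmoid"),
                           sigmoid = NULL, kappa = 100) {
  organ <- match.arg(organ)
  regularity <- match.arg(regularity)
  nonlinearity <- match.arg(nonlinearity)
  if (!is.finite(r0) || r0 <= 0) stop("r0 must be positive")
  if (!is.finite(kappa) || kappa < 1) stop("kappa must be >= 1")
  if (organ == "canal") {
    if (is.null(sv) || is.null(sa) || !is.null(sj)) {
      stop("canal afferents take coefficients (sv, sa) only")
    }
  } else {
    if (is.null(sa) || is.null(sj) || !is.null(sv)) {
      stop("otolith afferents take coefficients (sa, sj) only")
    }
  }
  if (nonlinearity == "sigmoid" && !inherits(sigmoid, "sigmoid_params")) {
    stop("sigmoid nonlinearity requires sigmoid_params")
  }
  structure(list(organ = organ, regularity = regularity, r0 = r0,
                 sv = sv, sa = sa, sj = sj, lead = lead,
                 nonlinearity = nonlinearity, sigmoid = sigmoid,
                 kappa = kappa),
            class = "afferent_truth")
}

#' Instantaneous rate of an afferent for a stimulus (ground-truth forward model)
#'
#' Linear stage applied to the stimulus advanced by the response lead,
#' then the static nonlinearity.
#' @param truth an [afferent_truth()]
#' @param stim a `stimulus_trace`
#' @return numeric rate on the stimulus grid, sp/s
#' @export
afferent_rate <- function(truth, stim) {
  if (!inherits(stim, "stimulus_trace")) stop("stim must be a stimulus_trace")
  fs <- stim$sample_rate
  k <- round(truth$lead * fs)
  if (truth$organ == "canal") {
    drive <- truth$r0 +
      truth$sv * advance_series(stim$pitch_velocity, k) +
      truth$sa * advance_series(stim$pitch_acceleration, k)
  } else {
    drive <- truth$r0 +
      truth$sa * advance_series(stim$linear_acceleration, k) +
      truth$sj * advance_series(stim$jerk, k)
  }
  if (truth$nonlinearity == "linear-rectified") pmax(drive, 0) else tsig(drive, truth$sigmoid)
}

#' Simulate a spike train from an afferent and a stimulus
#'
#' Spikes are drawn by time rescaling: the cumulative intensity transforms
#' the record to operational time, in which interspike intervals are iid
#' gamma with shape `kappa` and unit mean. The expected spike count over any
#' window equals the integral of the instantaneous rate, and the resting ISI
#' CV is approximately 1/sqrt(kappa).
#'
#' @inheritParams afferent_rate
#' @param seed RNG seed; identical truth + stimulus + seed reproduce the
#'   spike train exactly
#' @return `simulated_recording`: list(stimulus, spike_times, truth, seed)
#' @export
simulate_afferent <- function(truth, stim, seed) {
  rate <- afferent_rate(truth, stim)
  set.seed(as.integer(seed))
  dt <- 1 / stim$sample_rate
  n <- length(rate)
  # trapezoidal cumulative intensity: lam[i] is operational time at t[i]
  lam <- c(0, cumsum((rate[-1] + rate[-n]) / 2)) * dt
  total <- lam[length(lam)]
  kappa <- truth$kappa
  draw <- function(m) stats::rgamma(m, shape = kappa, rate = kappa)
  s <- cumsum(draw(ceiling(total + 6 * sqrt(max(total, 1) / kappa) + 50)))
  while (s[length(s)] < total) s <- c(s, s[length(s)] + cumsum(draw(100)))
  s <- s[s <= total]
  idx <- findInterval(s, lam)
  idx <- pmax(idx, 1L)
  dl <- lam[pmin(idx + 1L, length(lam))] - lam[idx]
  frac <- ifelse(dl > 0, (s - lam[idx]) / dl, 1)
  spikes <- stim$t[idx] + pmin(pmax(frac, 0), 1) * dt
  spikes <- spikes[!duplicated(spikes)]
  structure(list(stimulus = stim, spike_times = spikes, truth = truth,
                 seed = as.integer(seed)),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat(sprintf("simulated_recording: %s %s afferent, %d spikes over %.1f s (%s)\n",
              x$truth$regularity, x$truth$organ, length(x$spike_times),
              length(x$stimulus$t) / x$stimulus$sample_rate,
              x$stimulus$condition))
  invisible(x)
}

## ---- cohort -------------------------------------------------------------

#' Cohort configuration
#'
#' Class counts default to the study design emulated by the package:
#' 15 regular + 17 irregular canal and 9 regular + 14 irregular otolith
#' afferents, each recorded in every condition with identical ground truth
#' (within-afferent design). Ground-truth parameter ranges are drawn
#' uniformly within per-class ranges; irregular otolith gains are set high
#' enough that the running stimulus drives inhibitory cutoff.
#'
#' @param n_regular_canal,n_irregular_canal,n_regular_otolith,n_irregular_otolith
#'   class counts
#' @param conditions condition labels to record (subset of
#'   [STIMULUS_CONDITIONS])
#' @param duration record length per condition, s
#' @param rest_duration stimulus-free record length for resting-discharge
#'   statistics, s
#' @param params a [stimulus_params()]
#' @param kappa_regular,kappa_irregular gamma shapes for the two regularity
#'   classes (resting CV ~= 1/sqrt(kappa): 0.10 and 0.33 at the defaults,
#'   either side of the 0.15 CV* cutoff)
#' @param ranges per-class ground-truth ranges (list of lists with elements
#'   r0, gain, ratio2: bias range, primary-coefficient range, and the ratio
#'   of the secondary to the primary coefficient; with gain_relative = TRUE
#'   the gain range is in units of r0, keeping every member's walking-range
#'   drive clear of cutoff while running bursts reach it; for the irregular
#'   otolith class a fraction sigmoid_frac of members are high-sensitivity
#'   saturating cells with erf-sigmoid ground truth and gain sigmoid_gain
#'   times r0 -- the cutoff-regime units whose running responses a passive
#'   linear model cannot predict)
#' @export
cohort_config <- function(n_regular_canal = 15, n_irregular_canal = 17,
                          n_regular_otolith = 9, n_irregular_otolith = 14,
                          conditions = STIMULUS_CONDITIONS,
                          duration = 60, rest_duration = 30,
                          params = stimulus_params(),
                          kappa_regular = 100, kappa_irregular = 16,
                          ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- list(
      regular_canal    = list(r0 = c(70, 100), gain = c(0.3, 0.5),  ratio2 = 0.01),
      irregular_canal  = list(r0 = c(60, 90),  gain = c(0.8, 1.2),  ratio2 = 0.015),
      regular_otolith  = list(r0 = c(60, 90),  gain = c(60, 100),   ratio2 = 0.005),
      irregular_otolith = list(r0 = c(70, 90), gain = c(2.2, 2.6), gain_relative = TRUE,
                               ratio2 = 0.004, sigmoid_frac = 0.3,
                               sigmoid_gain = c(4.5, 6))
    )
  }
  counts <- c(regular_canal = n_regular_canal, irregular_canal = n_irregular_canal,
              regular_otolith = n_regular_otolith, irregular_otolith = n_irregular_otolith)
  if (any(counts < 0) || sum(counts) == 0) stop("class counts must be non-negative and not all zero")
  conditions <- match.arg(conditions, STIMULUS_CONDITIONS, several.ok = TRUE)
  structure(list(counts = counts, conditions = conditions, duration = duration,
                 rest_duration = rest_duration, params = params,
                 kappa_regular = kappa_regular, kappa_irregular = kappa_irregular,
                 ranges = ranges),
            class = "cohort_config")
}

#' Generate a synthetic afferent cohort
#'
#' Each afferent keeps identical ground truth in every condition; condition
#' stimuli are generated once per cohort and shared across afferents (a
#' common motion trajectory, as in a shared experimental session). Every
#' afferent also receives a stimulus-free resting recording. The analytic
#' resting CV (1/sqrt(kappa)) of each class is checked against the 0.15
#' regularity cutoff.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed; all per-recording sub-seeds derive from it
#' @return list with `recordings` (recordings[[afferent_id]][[condition]]),
#'   `rest` (recordings[[afferent_id]]), `truths`, `manifest` (data.frame)
#'   and the config/seed used
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  set.seed(as.integer(seed))
  classes <- names(config$counts)
  truths <- list()
  for (cl in classes) {
    n <- config$counts[[cl]]
    if (n == 0) next
    rg <- config$ranges[[cl]]
    organ <- if (grepl("canal", cl)) "canal" else "otolith"
    regularity <- if (grepl("irregular", cl)) "irregular" else "regular"
    kappa <- if (regularity == "irregular") config$kappa_irregular else config$kappa_regular
    cv <- 1 / sqrt(kappa)
    if (regularity == "irregular" && cv < 0.15) {
      stop("kappa_irregular implies resting CV below the 0.15 cutoff")
    }
    if (regularity == "regular" && cv >= 0.15) {
      stop("kappa_regular implies resting CV at or above the 0.15 cutoff")
    }
    for (i in seq_len(n)) {
      r0 <- stats::runif(1, rg$r0[1], rg$r0[2])
      use_sigmoid <- !is.null(rg$sigmoid_frac) && i <= round(rg$sigmoid_frac * n)
      g <- if (use_sigmoid) {
        stats::runif(1, rg$sigmoid_gain[1], rg$sigmoid_gain[2]) * r0
      } else {
        gg <- stats::runif(1, rg$gain[1], rg$gain[2])
        if (isTRUE(rg$gain_relative)) gg * r0 else gg
      }
      id <- sprintf("%s_%02d", cl, i)
      truths[[id]] <- if (organ == "canal") {
        afferent_truth("canal", regularity, r0, sv = g, sa = g * rg$ratio2,
                       kappa = kappa)
      } else if (use_sigmoid) {
        afferent_truth("otolith", regularity, r0, sa = g, sj = g * rg$ratio2,
                       nonlinearity = "sigmoid", sigmoid = resting_sigmoid(r0),
                       kappa = kappa)
      } else {
        afferent_truth("otolith", regularity, r0, sa = g, sj = g * rg$ratio2,
                       kappa = kappa)
      }
    }
  }
  n_aff <- length(truths)
  conds <- config$conditions
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(conds) + n_aff * (length(conds) + 1))
  stim <- list()
  for (j in seq_along(conds)) {
    stim[[conds[j]]] <- generate_stimulus(conds[j], config$duration,
                                          config$params, seed = sub_seeds[j])
  }
  rest_params <- config$params
  rest_params$accel_sd_walk <- 0
  rest_params$rot_sd_walk <- 0
  rest_stim <- generate_stimulus("passive_low", config$rest_duration, rest_params, seed = 1)

  recordings <- list()
  rest <- list()
  manifest <- list()
  si <- length(conds)
  for (id in names(truths)) {
    recordings[[id]] <- list()
    for (cond in conds) {
      si <- si + 1
      recordings[[id]][[cond]] <- simulate_afferent(truths[[id]], stim[[cond]], sub_seeds[si])
      manifest[[length(manifest) + 1]] <- data.frame(
        afferent_id = id, organ = truths[[id]]$organ,
        regularity = truths[[id]]$regularity, condition = cond,
        epoch = "stimulated", seed = sub_seeds[si],
        duration_s = config$duration, r0_true = truths[[id]]$r0
      )
    }
    si <- si + 1
    rest[[id]] <- simulate_afferent(truths[[id]], rest_stim, sub_seeds[si])
    manifest[[length(manifest) + 1]] <- data.frame(
      afferent_id = id, organ = truths[[id]]$organ,
      regularity = truths[[id]]$regularity, condition = "passive_low",
      epoch = "rest", seed = sub_seeds[si],
      duration_s = config$rest_duration, r0_true = truths[[id]]$r0
    )
  }
  list(recordings = recordings, rest = rest, truths = truths,
       manifest = do.call(rbind, manifest), config = config, seed = seed)
}

## ---- spike file interface ------------------------------------------------

#' Write / read spike times as plain text (one time in seconds per line)
#' @param spike_times numeric vector, s
#' @param path file path
#' @export
write_spike_times <- function(spike_times, path) {
  writeLines(format(spike_times, digits = 12, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  x <- as.numeric(readLines(path))
  if (any(!is.finite(x)) || is.unsorted(x, strictly = TRUE)) {
    stop("spike file must contain strictly increasing finite times")
  }
  x
}
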