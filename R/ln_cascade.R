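#' Estimate the response lead by cross-correlation
#'
#' Finds the shift of the head-motion signal that maximizes its correlation
#' with the firing rate, within a symmetric search window. Positive lead
#' means firing precedes motion (the motion signal must be advanced to
#' align). The integer-sample peak is refined by parabolic interpolation.
#'
#' @param rate a [rate_trace()] (or numeric vector)
#' @param stim_channel numeric motion channel on the same grid
#' @param fs sampling rate, Hz (taken from `rate` when available)
#' @param max_lag half-width of the search window, s
#' @return lead, s
#' @export
estimate_response_lag <- function(rate, stim_channel, fs = NULL, max_lag = 0.05) {
  r <- if (inherits(rate, "rate_trace")) rate$rate else rate
  if (is.null(fs)) {
    if (!inherits(rate, "rate_trace")) stop("fs required for a bare rate vector")
    fs <- rate$sample_rate
  }
  n <- length(r)
  if (length(stim_channel) != n) stop("rate and stimulus must share a grid")
  if (stats::sd(r) == 0 || stats::sd(stim_channel) == 0) {
    stop("flat rate or flat stimulus: correlation undefined")
  }
  r <- r - mean(r)
  s <- stim_channel - mean(stim_channel)
  kmax <- round(max_lag * fs)
  lags <- (-kmax):kmax
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(r[1:(n - k)] * s[(1 + k):n]) else sum(r[(1 - k):n] * s[1:(n + k)])
  }, numeric(1))
  m <- which.max(cc)
  delta <- 0
  if (m > 1 && m < length(cc)) {
    denom <- cc[m - 1] - 2 * cc[m] + cc[m + 1]
    if (denom < 0) delta <- 0.5 * (cc[m - 1] - cc[m + 1]) / denom
  }
  (lags[m] + delta) / fs
}

#' Linear-range sample mask
#'
#' Keeps samples whose stimulus value lies within one standard deviation of
#' the stimulus mean; the neuron's response over this range is treated as
#' linear.
#' @param stim_channel numeric stimulus channel
#' @return logical mask
#' @export
determine_linear_range <- function(stim_channel) {
  s <- stats::sd(stim_channel)
  if (!is.finite(s) || s == 0) stop("zero-variance stimulus: linear range undefined")
  abs(stim_channel - mean(stim_channel)) <= s
}

#' Fit the linear stage of the LN cascade
#'
#' Least squares of the rate on a single lead-aligned stimulus channel over
#' the masked (linear-range) samples: rate ~ St * H + r0.
#' @param rate a [rate_trace()] (or numeric vector)
#' @param stim_channel numeric channel, already lead-aligned
#' @param mask logical sample mask
#' @return list(st, r0)
#' @export
fit_linear_stage <- function(rate, stim_channel, mask = NULL) {
  y <- if (inherits(rate, "rate_trace")) rate$rate else rate
  if (is.null(mask)) mask <- rep(TRUE, length(y))
  if (!any(mask)) stop("empty linear-range mask")
  x <- stim_channel[mask]
  y <- y[mask]
  if (stats::var(x) == 0) stop("degenerate design: zero-variance stimulus in mask")
  st <- stats::cov(x, y) / stats::var(x)
  list(st = st, r0 = mean(y) - st * mean(x))
}

#' Average the firing rate within stimulus bins
#'
#' Bins are aligned to multiples of `bin_width` (the default for otolith
#' acceleration channels is 0.0004 g); empty bins are dropped, so the bin
#' counts sum to the number of analyzed samples.
#' @param rate a [rate_trace()] (or numeric vector)
#' @param stim_channel numeric channel, lead-aligned
#' @param bin_width bin width in stimulus units
#' @return `binned_tuning`: bin_edges, bin_centers, mean_rate, count
#' @export
bin_stimulus_response <- function(rate, stim_channel, bin_width = 0.0004) {
  y <- if (inherits(rate, "rate_trace")) rate$rate else rate
  if (!length(y)) stop("empty input")
  if (bin_width <= 0) stop("bin_width must be positive")
  idx <- floor(stim_channel / bin_width)
  agg_mean <- tapply(y, idx, mean)
  agg_n <- tapply(y, idx, length)
  lev <- as.numeric(names(agg_mean))
  ord <- order(lev)
  lev <- lev[ord]
  structure(list(
    bin_edges = c(lev, lev[length(lev)] + 1) * bin_width,
    bin_centers = (lev + 0.5) * bin_width,
    mean_rate = as.numeric(agg_mean[ord]),
    count = as.integer(agg_n[ord]),
    bin_width = bin_width
  ), class = "binned_tuning")
}

#' Fit the erf-sigmoid static nonlinearity
#'
#' Nonlinear least squares of Tsig(x) = c3 * pnorm((x - c2)/sqrt(c1)) to
#' (x, y) pairs, by default the binned mean rates weighted by bin counts.
#' Initialization: c3 at the maximum response, c2 at the half-maximum
#' crossing, c1 at (range/4)^2; bounds keep c1 and c3 positive; the
#' optimizer is deterministic (no random restarts). If the data carry no
#' sigmoidal curvature (e.g. a purely linear operating range) and the fit
#' fails, a wide quasi-linear sigmoid matched to the local slope is
#' returned with `converged = FALSE` noted in the diagnostics.
#'
#' @param x stimulus or linear-prediction values (or a `binned_tuning`)
#' @param y mean rates (ignored when `x` is a `binned_tuning`)
#' @param weights fit weights (bin counts when binned input is given)
#' @param tol convergence tolerance
#' @return a [sigmoid_params()] with attribute `diagnostics`
#'   (list(converged, rss))
#' @export
fit_sigmoid <- function(x, y = NULL, weights = NULL, tol = 1e-8) {
  if (inherits(x, "binned_tuning")) {
    weights <- x$count
    y <- x$mean_rate
    x <- x$bin_centers
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep] else weights <- rep(1, length(x))
  if (length(x) < 4) stop("need at least 4 informative points to fit the sigmoid")
  ord <- order(x)
  xs <- x[ord]; ysr <- y[ord]; ws <- weights[ord]
  # weighted running mean stabilises the half-max crossing when bins are
  # narrow and individually noisy
  span <- max(5L, round(length(xs) / 50))
  kern <- rep(1, span)
  ysm <- as.numeric(stats::filter(ysr * ws, kern, sides = 2)) /
    as.numeric(stats::filter(ws, kern, sides = 2))
  ysm[is.na(ysm)] <- ysr[is.na(ysm)]
  c3_0 <- max(ysm)
  if (c3_0 <= 0) stop("no dynamic range in the response")
  half_idx <- which(ysm >= c3_0 / 2)[1]
  c2_0 <- if (is.na(half_idx)) stats::median(x) else xs[half_idx]
  c1_0 <- (diff(range(x)) / 4)^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ c3 * pnorm((x - c2) / sqrt(c1)),
      start = list(c1 = c1_0, c2 = c2_0, c3 = c3_0),
      lower = c(c1 = 1e-12, c2 = -Inf, c3 = 1e-9),
      weights = weights,
      control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol, maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # quasi-linear fallback: a very wide sigmoid matching the local
    # (weighted) slope and passing through the weighted operating point
    mx <- stats::weighted.mean(x, weights)
    my <- stats::weighted.mean(y, weights)
    sl <- sum(weights * (x - mx) * (y - my)) / sum(weights * (x - mx)^2)
    if (!is.finite(sl) || sl <= 0) stop("sigmoid fit failed: data without dynamic range")
    c3 <- 4 * max(y)
    sqc1 <- c3 / (sl * sqrt(2 * pi))
    q <- min(max(my / c3, 1e-6), 1 - 1e-6)
    c2 <- mx - sqc1 * stats::qnorm(q)
    out <- sigmoid_params(sqc1^2, c2, c3)
    attr(out, "diagnostics") <- list(converged = FALSE, rss = NA_real_)
    return(out)
  }
  cf <- stats::coef(fit)
  out <- sigmoid_params(cf[["c1"]], cf[["c2"]], cf[["c3"]])
  attr(out, "diagnostics") <- list(converged = TRUE,
                                   rss = sum(weights * stats::residuals(fit)^2))
  out
}

#' Fit the full linear-nonlinear cascade model
#'
#' Composite procedure: (1) estimate the response lead by cross-correlation
#' and advance the organ's primary motion channel (pitch velocity for canal,
#' net linear acceleration for otolith); (2) restrict to the linear range
#' (stimulus within one SD of its mean) and fit the linear stage
#' r(t) = St H(t) + r0; (3) average the firing rate within stimulus bins
#' (0.0004 g for otolith channels; stimulus SD / 50 for canal channels) and
#' fit the erf sigmoid to the binned response against the linear
#' prediction; (4) predict N(t) = Tsig(St H(t) + r0) and evaluate its VAF.
#'
#' Because a strongly driven afferent is not perfectly linear even within
#' one stimulus SD, the linear-stage gain estimated there is attenuated by
#' sigmoid curvature. With `curvature_correction = TRUE` (default) the gain
#' is corrected by the Bussgang-type factor sqrt(1 + sigma_m^2 / c1), where
#' sigma_m is the masked linear-prediction SD and c1 the fitted sigmoid
#' width — exact for Gaussian drive through an erf nonlinearity — and the
#' sigmoid is refit once on the corrected prediction.
#'
#' Response bias is the firing rate of the cascade at zero head motion,
#' Tsig(r0); the modulation is the slope of the sigmoid at the same
#' operating point through the linear stage, St * Tsig'(r0), so it is
#' unit-commensurate with the linear model's gain.
#'
#' @param rate a [rate_trace()] on the stimulus grid
#' @param stim a `stimulus_trace`
#' @param organ "canal" or "otolith"
#' @param bin_width stimulus bin width; default 0.0004 g (otolith) or
#'   stimulus SD / 50 (canal)
#' @param max_lag lead search half-window, s
#' @param curvature_correction apply the gain de-attenuation (see Details)
#' @return `ln_model`: st, r0, lead, sigmoid ([sigmoid_params()]), bias,
#'   modulation_slope, vaf (LN prediction), vaf_linear (raw linear-stage
#'   prediction), linear_range_mask
#' @export
fit_ln_model <- function(rate, stim, organ = c("canal", "otolith"),
                         bin_width = NULL, max_lag = 0.05,
                         curvature_correction = TRUE) {
  organ <- match.arg(organ)
  if (length(rate$rate) != length(stim$t)) stop("rate and stimulus must share a grid")
  fs <- stim$sample_rate
  h <- if (organ == "canal") stim$pitch_velocity else stim$linear_acceleration
  lead <- estimate_response_lag(rate, h, fs, max_lag)
  h <- advance_series(h, round(lead * fs))
  mask <- determine_linear_range(h)
  lin <- fit_linear_stage(rate, h, mask)
  st <- lin$st
  r0 <- lin$r0
  if (is.null(bin_width)) {
    bin_width <- if (organ == "otolith") 0.0004 else stats::sd(h) / 50
  }
  tune <- bin_stimulus_response(rate, h, bin_width)
  sig <- fit_sigmoid(st * tune$bin_centers + r0, tune$mean_rate, weights = tune$count)
  if (curvature_correction) {
    sigma_m <- abs(st) * stats::sd(h[mask])
    factor <- sqrt(1 + sigma_m^2 / sig$c1)
    st <- st * factor
    sig <- fit_sigmoid(st * tune$bin_centers + r0, tune$mean_rate, weights = tune$count)
  }
  linpred <- st * h + r0
  ln_pred <- tsig(linpred, sig)
  structure(list(
    organ = organ, st = st, r0 = r0, lead = lead, sigmoid = sig,
    bias = tsig(r0, sig), modulation_slope = st * tsig_slope(r0, sig),
    vaf = vaf(rate$rate, ln_pred), vaf_linear = vaf(rate$rate, linpred),
    linear_range_mask = mask, bin_width = bin_width
  ), class = "ln_model")
}

#' Predict the LN-cascade firing rate for a stimulus
#'
#' N(t) = Tsig(St H(t + lead) + r0); bounded in [0, c3], never negative.
#' @param object an `ln_model`
#' @param stim a `stimulus_trace`
#' @param ... unused
#' @export
predict.ln_model <- function(object, stim, ...) {
  h <- if (object$organ == "canal") stim$pitch_velocity else stim$linear_acceleration
  h <- advance_series(h, round(object$lead * stim$sample_rate))
  tsig(object$st * h + object$r0, object$sigmoid)
}

#' @export
print.ln_model <- function(x, ...) {
  cat(sprintf("ln_model (%s): St = %.4g, r0 = %.1f sp/s, lead = %.1f ms\n",
              x$organ, x$st, x$r0, 1000 * x$lead))
  cat(sprintf("  sigmoid c1 = %.4g, c2 = %.4g, c3 = %.4g\n",
              x$sigmoid$c1, x$sigmoid$c2, x$sigmoid$c3))
  cat(sprintf("  bias = %.1f sp/s, modulation = %.4g, VAF = %.3f (linear %.3f)\n",
              x$bias, x$modulation_slope, x$vaf, x$vaf_linear))
  invisible(x)
}
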