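#' Organ-specific motion channels for the linear rate model
#' @keywords internal
organ_channels <- function(stim, organ) {
  if (organ == "canal") {
    list(x1 = stim$pitch_velocity, x2 = stim$pitch_acceleration,
         names = c("sv", "sa"))
  } else {
    list(x1 = stim$linear_acceleration, x2 = stim$jerk,
         names = c("sa", "sj"))
  }
}

#' Fit the least-squares linear rate model of an afferent
#'
#' Ordinary least squares of the estimated firing rate on the organ's two
#' motion channels plus an intercept: velocity and acceleration for canal
#' afferents, linear acceleration and jerk for otolith afferents. The fit
#' is restricted to samples where the rate exceeds `min_rate` (default
#' 10 sp/s) so that epochs potentially driven into inhibitory cutoff do not
#' distort the linear estimate. The restriction is applied per sample,
#' after any lead alignment.
#'
#' By default no lead alignment is applied (`lead = 0`): the two-channel
#' model absorbs small response leads into the derivative coefficient (a
#' shift by tau is, to first order, equivalent to adding tau times the
#' derivative channel), so shifting before a two-channel fit changes the
#' coefficient representation without improving the fit. Pass a numeric
#' lead in seconds, or `lead = "auto"` to align by cross-correlation on the
#' primary channel first.
#'
#' @param rate a [rate_trace()] on the stimulus grid
#' @param stim a `stimulus_trace`
#' @param organ "canal" or "otolith"
#' @param min_rate firing-rate restriction, sp/s
#' @param lead 0 (default), a lead in seconds, or "auto"
#' @param min_samples minimum number of samples above `min_rate`
#' @param vif_bound flag multicollinearity when any VIF exceeds this
#' @return `linear_rate_model`: bias `b`, named coefficient pair, `lead`,
#'   `fit_mask`, `vaf` (on the fitted samples), `vif` per regressor, and a
#'   residual-vs-fit diagnostic (correlation of residuals with fitted
#'   values)
#' @export
fit_linear_rate_model <- function(rate, stim, organ = c("canal", "otolith"),
                                  min_rate = 10, lead = 0,
                                  min_samples = 100, vif_bound = 10) {
  organ <- match.arg(organ)
  if (length(rate$rate) != length(stim$t)) stop("rate and stimulus must share a grid")
  ch <- organ_channels(stim, organ)
  fs <- stim$sample_rate
  if (identical(lead, "auto")) {
    lead <- estimate_response_lag(rate, ch$x1, fs)
  }
  k <- round(lead * fs)
  x1 <- advance_series(ch$x1, k)
  x2 <- advance_series(ch$x2, k)
  y <- rate$rate
  mask <- y > min_rate
  if (sum(mask) < min_samples) stop("too few samples above the firing-rate restriction")
  if (stats::var(x1[mask]) == 0 || stats::var(x2[mask]) == 0) {
    stop("degenerate design: zero-variance regressor")
  }
  fit <- stats::lm.fit(cbind(1, x1[mask], x2[mask]), y[mask])
  coefs <- fit$coefficients
  r12 <- stats::cor(x1[mask], x2[mask])
  vif <- rep(1 / (1 - r12^2), 2)
  names(vif) <- ch$names
  if (any(vif > vif_bound)) {
    warning("severe multicollinearity: VIF above ", vif_bound)
  }
  fitted <- fit$fitted.values
  model <- structure(list(
    organ = organ, b = unname(coefs[1]),
    coef = stats::setNames(unname(coefs[2:3]), ch$names),
    lead = lead, fit_mask = mask,
    vaf = vaf(y[mask], fitted), vif = vif,
    n_used = sum(mask),
    diagnostics = list(resid_fit_cor = stats::cor(fit$residuals, fitted))
  ), class = "linear_rate_model")
  model
}

#' Response modulation (gain) of a linear rate model at a frequency
#'
#' For canal afferents St = sqrt(Sv^2 + (2 pi f Sa)^2), in (sp/s)/(deg/s);
#' for otolith afferents the analogous combination of the acceleration and
#' jerk coefficients, in (sp/s)/g.
#' @param model a `linear_rate_model` (or a list with a 2-vector `coef`)
#' @param f frequency, Hz (>= 0)
#' @return scalar gain St
#' @export
gain_at_frequency <- function(model, f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  sqrt(model$coef[[1]]^2 + (2 * pi * f * model$coef[[2]])^2)
}

#' Predict the firing rate from a linear rate model
#'
#' With `rectify = FALSE` the raw linear prediction is returned, which may
#' be negative; such impossible negative rates are the diagnostic signature
#' of inhibitory cutoff. With `rectify = TRUE` the prediction is clipped at
#' zero.
#' @param model a `linear_rate_model`
#' @param stim a `stimulus_trace` with the organ's channels
#' @param rectify clip at zero?
#' @return numeric prediction on the stimulus grid
#' @export
predict_linear_rate <- function(model, stim, rectify = FALSE) {
  ch <- organ_channels(stim, model$organ)
  k <- round(model$lead * stim$sample_rate)
  pred <- model$b + model$coef[[1]] * advance_series(ch$x1, k) +
    model$coef[[2]] * advance_series(ch$x2, k)
  if (rectify) pmax(pred, 0) else pred
}

#' @export
predict.linear_rate_model <- function(object, stim, rectify = FALSE, ...) {
  predict_linear_rate(object, stim, rectify)
}

#' VAF and VIF diagnostics for a fitted model
#'
#' VAF = 1 - var(observed - predicted)/var(observed). VIF_j = 1/(1 - R^2_j)
#' where R^2_j is from regressing regressor j on the remaining columns of
#' the design.
#' @param observed,predicted equal-length numeric vectors
#' @param design optional numeric matrix of regressors (>= 2 columns) for
#'   VIF
#' @return list(vaf, vif)
#' @export
model_diagnostics <- function(observed, predicted, design = NULL) {
  out <- list(vaf = vaf(observed, predicted), vif = NULL)
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (ncol(design) < 2) stop("VIF needs at least two regressors")
    out$vif <- vapply(seq_len(ncol(design)), function(j) {
      r2 <- summary(stats::lm(design[, j] ~ design[, -j, drop = FALSE]))$r.squared
      1 / (1 - r2)
    }, numeric(1))
  }
  out
}

#' @export
print.linear_rate_model <- function(x, ...) {
  cat(sprintf("linear_rate_model (%s): b = %.2f sp/s, %s = %.4g, %s = %.4g\n",
              x$organ, x$b, names(x$coef)[1], x$coef[[1]],
              names(x$coef)[2], x$coef[[2]]))
  cat(sprintf("  lead %.1f ms, VAF %.3f on %d samples, max VIF %.2f\n",
              1000 * x$lead, x$vaf, x$n_used, max(x$vif)))
  invisible(x)
}
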