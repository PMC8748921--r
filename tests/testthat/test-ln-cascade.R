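test_that("response lag is recovered from constructed shifts", {
  st <- cached_stimulus("walking", 60, 320)
  h <- st$pitch_velocity
  rt0 <- rate_trace(st$t, 50 + 0.5 * h)
  expect_equal(estimate_response_lag(rt0, h), 0, tolerance = 1.5e-3)
  # rate built from the stimulus advanced by 12 ms: firing precedes motion
  k <- 12
  n <- length(h)
  adv <- c(h[(k + 1):n], rep(h[n], k))
  rt <- rate_trace(st$t, 50 + 0.5 * adv)
  expect_lt(abs(estimate_response_lag(rt, h) - 0.012), 1.5e-3)
  expect_error(estimate_response_lag(rate_trace(st$t, rep(10, n)), h), "flat")
})

test_that("linear-range mask keeps one SD around the mean", {
  set.seed(21)
  g <- rnorm(2e5)
  expect_equal(mean(determine_linear_range(g)), 2 * pnorm(1) - 1, tolerance = 0.01)
  u <- runif(2e5, -1, 1)     # SD = 1/sqrt(3)
  mask <- determine_linear_range(u)
  expect_equal(max(abs(u[mask])), 1 / sqrt(3), tolerance = 0.01)
  expect_error(determine_linear_range(rep(2, 10)), "zero-variance")
})

test_that("linear stage recovers noiseless slope and intercept", {
  set.seed(22)
  x <- rnorm(5000)
  y <- 0.9 * x + 70
  mask <- determine_linear_range(x)
  fit <- fit_linear_stage(y, x, mask)
  expect_equal(fit$st, 0.9, tolerance = 1e-10)
  expect_equal(fit$r0, 70, tolerance = 1e-10)
  # zero-slope data
  fit0 <- fit_linear_stage(rep(55, 5000) + 0 * x, x, mask)
  expect_equal(fit0$st, 0, tolerance = 1e-10)
  expect_equal(fit0$r0, 55, tolerance = 1e-10)
  expect_error(fit_linear_stage(y, x, rep(FALSE, 5000)), "empty")
})

test_that("masking out the cutoff region leaves linear-stage estimates unbiased", {
  set.seed(23)
  x <- rnorm(5e4, sd = 1)
  drive <- 30 + 40 * x          # deep cutoff below x = -0.75
  observed <- pmax(drive, 0)
  mask <- abs(x) <= 0.5         # well inside the linear region
  fit <- fit_linear_stage(observed, x, mask)
  ref <- fit_linear_stage(drive, x, mask)   # unclipped ground truth
  expect_equal(fit$st, ref$st, tolerance = 1e-10)
  expect_equal(fit$r0, ref$r0, tolerance = 1e-10)
})

test_that("stimulus-response binning averages within bins", {
  # hand example: two wide bins
  bt <- bin_stimulus_response(c(20, 40, 60), c(-0.01, -0.01, 0.01), bin_width = 0.02)
  expect_equal(bt$mean_rate, c(30, 60))
  expect_equal(bt$count, c(2L, 1L))
  expect_equal(sum(bt$count), 3L)
  # all samples in one bin -> overall mean
  one <- bin_stimulus_response(c(10, 20, 30), c(0.0001, 0.0002, 0.00005), bin_width = 1)
  expect_equal(one$mean_rate, 20)
  # default otolith width produces 0.0004-aligned edges
  x <- seq(-0.002, 0.002, by = 0.0001)
  bt4 <- bin_stimulus_response(seq_along(x), x)
  expect_true(all(abs(bt4$bin_edges / 0.0004 - round(bt4$bin_edges / 0.0004)) < 1e-12))
  expect_error(bin_stimulus_response(numeric(0), numeric(0)), "empty")
  expect_error(bin_stimulus_response(1, 1, bin_width = 0), "positive")
})

test_that("the erf sigmoid obeys its inflection and asymptote identities", {
  s <- sigmoid_params(400, 50, 120)
  expect_equal(tsig(50, s), 60)                 # Tsig(c2) = c3/2
  expect_equal(tsig(-1e4, s), 0, tolerance = 1e-12)
  expect_equal(tsig(1e4, s), 120, tolerance = 1e-12)
  # pnorm form equals the erf form
  erf <- function(z) 2 * pnorm(z * sqrt(2)) - 1
  x <- seq(-20, 130, by = 3)
  expect_equal(tsig(x, s), 120 / 2 * (1 + erf((x - 50) / sqrt(2 * 400))),
               tolerance = 1e-12)
  expect_error(sigmoid_params(-1, 0, 10), "c1")
  expect_error(sigmoid_params(1, 0, -10), "c3")
})

test_that("sigmoid fitting recovers generator parameters within 10%", {
  set.seed(24)
  x <- seq(-20, 130, length.out = 60)
  y <- tsig(x, 400, 50, 120) + rnorm(60, sd = 2)
  fit <- fit_sigmoid(x, y)
  expect_equal(fit$c1, 400, tolerance = 0.1)
  expect_equal(fit$c2, 50, tolerance = 0.1)
  expect_equal(fit$c3, 120, tolerance = 0.1)
  expect_true(attr(fit, "diagnostics")$converged)
  expect_error(fit_sigmoid(1:3, c(1, 2, 3)), "at least 4")
})

test_that("the full LN cascade recovers ground truth within 10% under running drive", {
  rn <- cached_stimulus("running", 200, 321)
  sig <- resting_sigmoid(100)
  truth <- afferent_truth("otolith", "irregular", r0 = 100, sa = 300, sj = 0,
                          lead = 0.015, nonlinearity = "sigmoid",
                          sigmoid = sig, kappa = 16)
  rt <- estimate_firing_rate(simulate_afferent(truth, rn, 322)$spike_times, rn$t)
  ln <- fit_ln_model(rt, rn, "otolith")
  expect_equal(ln$st, 300, tolerance = 0.1)
  expect_equal(ln$r0, 100, tolerance = 0.1)
  expect_equal(ln$lead, 0.015, tolerance = 0.1)
  expect_equal(ln$sigmoid$c1, sig$c1, tolerance = 0.1)
  expect_equal(ln$sigmoid$c2, sig$c2, tolerance = 0.1)
  expect_equal(ln$sigmoid$c3, sig$c3, tolerance = 0.1)
  # LN prediction bounded in [0, c3], never negative
  pred <- predict(ln, rn)
  expect_gte(min(pred), 0)
  expect_lte(max(pred), ln$sigmoid$c3 + 1e-9)
})

test_that("LN bias and modulation agree with linear estimates in the linear regime", {
  wk <- cached_stimulus("walking", 120, 323)
  tr <- afferent_truth("otolith", "regular", r0 = 70, sa = 90, sj = 0, kappa = 100)
  rt <- estimate_firing_rate(simulate_afferent(tr, wk, 324)$spike_times, wk$t)
  lin <- fit_linear_rate_model(rt, wk, "otolith")
  ln <- fit_ln_model(rt, wk, "otolith")
  expect_equal(ln$bias, lin$b, tolerance = 0.05)
  expect_equal(ln$modulation_slope, unname(lin$coef["sa"]), tolerance = 0.1)
  # near-linear operating range: LN adds essentially nothing over linear
  expect_equal(ln$vaf, ln$vaf_linear, tolerance = 0.02)
})

test_that("LN bias and modulation are condition-invariant for fixed ground truth", {
  wk <- cached_stimulus("walking", 120, 325)
  rn <- cached_stimulus("running", 120, 326)
  tr <- afferent_truth("otolith", "irregular", r0 = 75, sa = 190, sj = 0, kappa = 16)
  lns <- lapply(list(wk, rn), function(s) {
    rt <- estimate_firing_rate(simulate_afferent(tr, s, 327)$spike_times, s$t)
    fit_ln_model(rt, s, "otolith")
  })
  expect_equal(lns[[1]]$bias, lns[[2]]$bias, tolerance = 0.1)
  expect_equal(lns[[1]]$modulation_slope, lns[[2]]$modulation_slope, tolerance = 0.15)
})
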