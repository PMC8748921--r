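test_that("sinusoidal passive conditions are exact sinusoids at the configured amplitude", {
  st <- generate_stimulus("passive_sinusoid_translation", 10, stimulus_params())
  expect_equal(max(abs(st$linear_acceleration)), 0.2, tolerance = 1e-6)
  expect_true(all(st$pitch_velocity == 0))
  sp <- generate_stimulus("passive_sinusoid_pitch", 10, stimulus_params())
  expect_equal(max(abs(sp$pitch_velocity)), 40, tolerance = 1e-5)
  # time grid uniform and strictly increasing
  expect_true(all(diff(st$t) > 0))
  expect_lt(diff(range(diff(st$t))), 1e-10)
})

test_that("zero amplitude parameters give all-zero motion channels", {
  st <- generate_stimulus("walking", 5, quiet_params(), seed = 3)
  expect_true(all(st$linear_acceleration == 0))
  expect_true(all(st$pitch_velocity == 0))
  expect_true(all(st$jerk == 0))
  s2 <- generate_stimulus("passive_sinusoid_pitch", 5,
                          stimulus_params(sin_amp_dps = 0, sin_amp_g = 0))
  expect_true(all(s2$pitch_velocity == 0))
})

test_that("generator errors on bad inputs", {
  expect_error(generate_stimulus("jogging", 10), "arg")
  expect_error(generate_stimulus("walking", -1, stimulus_params(), seed = 1), "positive")
  expect_error(generate_stimulus("walking", 10, stimulus_params()), "seed")
  # unachievable tail target: heavier than Gaussian for the squash family
  expect_error(
    stimulus_tail_calibration(stimulus_params(
      tail_target_accel = c(passive = 0.2, walking = 0.05, running = 0.15))),
    "unachievable"
  )
})

test_that("analytic tail calibration hits the configured targets before sampling", {
  cal <- stimulus_tail_calibration(stimulus_params())
  expect_equal(cal$accel$passive$tail, 0.03, tolerance = 1e-6)
  expect_equal(cal$accel$walking$tail, 0.05, tolerance = 1e-6)
  expect_equal(cal$accel$running$tail, 0.15, tolerance = 1e-6)
  expect_equal(cal$rot$walking$tail, 0.02, tolerance = 1e-6)
  expect_equal(cal$rot$running$tail, 0.04, tolerance = 1e-6)
  # mixture respects the total-variance constraint
  p <- stimulus_params()
  expect_equal(
    sqrt((1 - p$mix_p) * cal$accel$running$sigma1^2 + p$mix_p * cal$accel$running$sigma2^2),
    p$sd_ratio_run, tolerance = 1e-6
  )
})

test_that("empirical running tail fraction matches the analytic mixture tail", {
  rn <- cached_stimulus("running", 300, 301)
  pl <- cached_stimulus("passive_low", 300, 302)
  frac <- tail_fraction(rn$linear_acceleration, pl$linear_acceleration, 1.5)
  expect_equal(frac, 0.15, tolerance = 0.25)  # Monte-Carlo band, single seed
})

test_that("matched condition pairs share SD while running carries more power", {
  p <- stimulus_params()
  wk <- cached_stimulus("walking", 300, 303)
  pl <- cached_stimulus("passive_low", 300, 302)
  rn <- cached_stimulus("running", 300, 301)
  expect_equal(sd(wk$linear_acceleration), sd(pl$linear_acceleration), tolerance = 0.05)
  expect_equal(sd(wk$linear_acceleration), p$accel_sd_walk, tolerance = 0.05)
  expect_gt(sd(rn$linear_acceleration), sd(wk$linear_acceleration))
  expect_gt(sd(rn$pitch_velocity), sd(wk$pitch_velocity))
  # heavy running tails: kurtosis well above Gaussian
  expect_gt(distribution_summary(rn$linear_acceleration)$kurtosis, 4)
})

test_that("derived channels equal the smoothed finite-difference derivative", {
  st <- cached_stimulus("walking", 20, 304)
  # recompute independently with the same shared convention
  vs <- vestaff:::smooth_channel(st$pitch_velocity, st$sample_rate, st$smooth_hz)
  n <- length(vs)
  dd <- (vs[3:n] - vs[1:(n - 2)]) * st$sample_rate / 2
  expect_equal(st$pitch_acceleration[2:(n - 1)], dd, tolerance = 1e-9)
})

test_that("spike simulation is reproducible and rate-count consistent", {
  st <- cached_stimulus("walking", 60, 305)
  tr <- afferent_truth("otolith", "regular", r0 = 70, sa = 90, sj = 0.5, kappa = 100)
  a <- simulate_afferent(tr, st, 11)
  b <- simulate_afferent(tr, st, 11)
  expect_identical(a$spike_times, b$spike_times)
  expect_true(all(diff(a$spike_times) > 0))
  expect_true(min(a$spike_times) >= 0 && max(a$spike_times) <= max(st$t) + 1e-3)
  # expected count equals integrated intensity within renewal error
  lam <- mean(afferent_rate(tr, st)) * 60
  expect_equal(length(a$spike_times), lam, tolerance = 4 * sqrt(lam) / lam)
})

test_that("unmodulated afferent fires at its resting discharge with low CV", {
  st <- rest_trace(30)
  tr <- afferent_truth("otolith", "regular", r0 = 80, sa = 100, sj = 0, kappa = 100)
  rec <- simulate_afferent(tr, st, 7)
  expect_equal(length(rec$spike_times) / 30, 80, tolerance = 0.05)
  isi <- diff(rec$spike_times)
  expect_equal(sd(isi) / mean(isi), 0.1, tolerance = 0.2)
})

test_that("sinusoidally driven canal afferent modulates at closed-form depth", {
  st <- generate_stimulus("passive_sinusoid_pitch", 30, stimulus_params())
  tr <- afferent_truth("canal", "regular", r0 = 80, sv = 0.5, sa = 0, kappa = 100)
  rt <- estimate_firing_rate(simulate_afferent(tr, st, 8)$spike_times, st$t)
  cyc <- cycle_modulation(rt, frequency = 1, folded = TRUE)
  expect_equal(cyc$modulation, 2 * 0.5 * 40, tolerance = 0.1)  # 2 Sv A
  expect_equal(cyc$mean_rate, 80, tolerance = 0.05)
})

test_that("resting CV follows 1/sqrt(kappa) and decreases with kappa", {
  st <- rest_trace(40)
  cvs <- sapply(c(4, 16, 64), function(k) {
    tr <- afferent_truth("otolith", "irregular", r0 = 70, sa = 1e-9, sj = 0,
                         kappa = k)
    isi <- diff(simulate_afferent(tr, st, 100 + k)$spike_times)
    sd(isi) / mean(isi)
  })
  expect_equal(cvs, 1 / sqrt(c(4, 16, 64)), tolerance = 0.12)
  expect_true(all(diff(cvs) < 0))
})

test_that("afferent_truth validates coefficient sets and parameters", {
  expect_error(afferent_truth("canal", "regular", 80, sa = 1, sj = 1, kappa = 9), "canal")
  expect_error(afferent_truth("otolith", "regular", 80, sv = 1, sa = 1, sj = 0), "otolith")
  expect_error(afferent_truth("canal", "regular", -5, sv = 1, sa = 0), "r0")
  expect_error(afferent_truth("canal", "regular", 80, sv = 1, sa = 0, kappa = 0.5), "kappa")
  expect_error(afferent_truth("otolith", "regular", 80, sa = 1, sj = 0,
                              nonlinearity = "sigmoid"), "sigmoid")
})

test_that("cohort generation honours counts, within-afferent design and determinism", {
  cfg <- cohort_config(n_regular_canal = 2, n_irregular_canal = 1,
                       n_regular_otolith = 1, n_irregular_otolith = 2,
                       conditions = c("passive_low", "running"),
                       duration = 10, rest_duration = 10)
  co <- generate_cohort(cfg, seed = 9)
  expect_length(co$truths, 6)
  expect_true(all(vapply(co$recordings, length, 1L) == 2))
  # same truth object in all conditions of one afferent
  id <- names(co$recordings)[1]
  expect_identical(co$recordings[[id]]$passive_low$truth,
                   co$recordings[[id]]$running$truth)
  co2 <- generate_cohort(cfg, seed = 9)
  expect_identical(co$recordings[[id]]$running$spike_times,
                   co2$recordings[[id]]$running$spike_times)
  expect_equal(nrow(co$manifest), 6 * 3)  # 2 conditions + rest per afferent
  expect_error(cohort_config(n_regular_canal = 0, n_irregular_canal = 0,
                             n_regular_otolith = 0, n_irregular_otolith = 0),
               "counts")
})

test_that("stimulus and spike files round-trip through the text interfaces", {
  st <- cached_stimulus("walking", 5, 306)
  f <- withr::local_tempfile(fileext = ".csv")
  write_stimulus_csv(st, f)
  back <- read_stimulus_csv(f, condition = "walking")
  expect_equal(back$pitch_velocity, st$pitch_velocity, tolerance = 1e-8)
  expect_equal(back$linear_acceleration, st$linear_acceleration, tolerance = 1e-8)
  tr <- afferent_truth("otolith", "regular", r0 = 60, sa = 80, sj = 0.4, kappa = 100)
  rec <- simulate_afferent(tr, st, 5)
  g <- withr::local_tempfile(fileext = ".txt")
  write_spike_times(rec$spike_times, g)
  expect_equal(read_spike_times(g), rec$spike_times, tolerance = 1e-9)
})
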