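# vestaff

Linear and linear–nonlinear (LN) encoding analysis of vestibular afferents
across passive head motion, walking and running — with a calibrated
synthetic-afferent simulator providing ground truth for every stage.

## The problem

Vestibular afferents signal head motion: semicircular-canal fibres encode
angular pitch velocity, otolith fibres the net gravito-inertial linear
acceleration. Under gentle passive stimulation a linear rate model
describes them well,

    canal:    fr(t) = b + Sv·H'(t) + Sa·H''(t)
    otolith:  fr(t) = b + Sa·H''(t) + Sj·H'''(t)

with frequency-resolved gain `St = sqrt(Sv² + (2πf·Sa)²)` (and the
acceleration/jerk analogue for otoliths). But running drives the
high-sensitivity irregular otolith fibres far outside that range: the
linear model predicts impossible negative rates, while the real cell
rectifies at zero (inhibitory cutoff) and saturates. Cutoff shows up as a
spike in the probability of zero firing rate and a mean rate *above* the
resting discharge. An LN cascade,

    N(t) = Tsig(St·H(t) + r0),   Tsig(x) = (c3/2)·[1 + erf((x − c2)/√(2·c1))]

restores a single, condition-invariant description: bias `Tsig(r0)` and
modulation `St·Tsig'(r0)`.

The package implements the full chain: Kaiser-window firing-rate
estimation, CV\* discharge-regularity classification (cutoff 0.15),
least-squares linear models with the >10 sp/s cutoff guard and VAF/VIF
diagnostics, the LN cascade (cross-correlation lag alignment, ±1 SD linear
range, 0.0004 g stimulus binning, weighted erf-sigmoid fit), head-motion
statistics (Welch spectra, cumulative-spectrum area, ±1.5 SD amplitude
tails, kurtosis, mean head orientation), and a cohort-level analysis
pipeline — plus a stimulus/afferent simulator whose amplitude distributions
are calibrated in closed form to the tail fractions that distinguish the
conditions (15% of running accelerations beyond ±1.5 SD of the
walking-matched passive reference, versus 5% walking and 3% passive).

## Worked example

Simulate a high-sensitivity irregular otolith afferent in a passive and a
running condition, fit the passive linear model, and compare its running
prediction with the LN cascade:

```r
library(vestaff)

params  <- stimulus_params()
passive <- generate_stimulus("passive_low", 120, params, seed = 1)
running <- generate_stimulus("running",     120, params, seed = 2)

truth <- afferent_truth("otolith", "irregular", r0 = 80, sa = 400, sj = 0,
                        nonlinearity = "sigmoid",
                        sigmoid = resting_sigmoid(80), kappa = 16)
rec_pas <- simulate_afferent(truth, passive, seed = 3)
rec_run <- simulate_afferent(truth, running, seed = 4)

rate_pas <- estimate_firing_rate(rec_pas$spike_times, passive$t)
rate_run <- estimate_firing_rate(rec_run$spike_times, running$t)

(lin <- fit_linear_rate_model(rate_pas, passive, organ = "otolith"))
#> linear_rate_model (otolith): b = 81.64 sp/s, sa = 329.9, sj = 0.1928
#>   lead 0.0 ms, VAF 0.835 on 113714 samples, max VIF 1.00

vaf(rate_run$rate, predict_linear_rate(lin, running))
#> [1] -0.890

(ln <- fit_ln_model(rate_run, running, organ = "otolith"))
#> ln_model (otolith): St = 389.4, r0 = 80.0 sp/s, lead = -0.4 ms
#>   sigmoid c1 = 3996, c2 = 80.59, c3 = 161.1
#>   bias = 79.9 sp/s, modulation = 395.9, VAF = 0.833 (linear -1.889)

tail_fraction(running$linear_acceleration, passive$linear_acceleration)
#> [1] 0.148
```

Reading the numbers: the passive fit recovers the resting discharge
(b ≈ 82 sp/s) and an attenuated acceleration gain (330 vs the generative
400, since even passive motion engages some sigmoid curvature); its
prediction of the running record is worse than predicting the mean
(VAF −0.89) because running bursts drive the cell into cutoff and
saturation. The LN cascade fitted on the running record recovers the
generative parameters — gain 389 vs 400, r0 80.0, sigmoid midpoint
c2 ≈ 80.6 vs 80, asymptote c3 ≈ 161 vs 160 — and predicts the same record
with VAF 0.83. Its bias (79.9 sp/s) matches the passive resting discharge:
one model describes both conditions. The running tail fraction (0.148)
shows the calibrated 15% of accelerations beyond ±1.5 SD of the passive
reference.

Cohort-level analysis (regularity classification, per-condition metrics,
linear and LN fits, class summaries and standard contrasts):

```r
report <- run_analysis(cohort_config(duration = 60), seed = 1, out_dir = "results/cohort")
```

A thin command-line wrapper with `simulate`, `fit-ln` and `run` commands is
installed at `inst/cli/vestaff.R`.

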