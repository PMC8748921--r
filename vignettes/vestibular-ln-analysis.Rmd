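---
title: "Linear and linear-nonlinear models of vestibular afferent encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear and linear-nonlinear models of vestibular afferent encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestaff)
```

# The scientific problem

Vestibular afferents carry head-motion signals from the inner ear to the
brainstem. Semicircular-canal fibres encode angular head velocity;
otolith fibres encode the net gravito-inertial linear acceleration. Within
each organ, fibres fall into two discharge-regularity classes — regular and
irregular — distinguished by the normalized coefficient of variation (CV\*)
of their resting interspike intervals, with irregular afferents showing the
higher sensitivities.

During locomotion, and especially running, head accelerations reach
amplitudes far beyond those of quiet passive stimulation. A linear rate
model fitted under gentle passive motion then predicts impossible negative
firing rates during running: the real cell instead rectifies at zero
(inhibitory cutoff) and saturates at high drive. Cutoff has two signatures:
a spike in the probability of zero firing rate, and a time-averaged rate
*above* the resting discharge, because the cell can modulate upward but not
below zero. A linear–nonlinear (LN) cascade — the linear stage followed by a
static erf-sigmoid — captures both, and with it the same bias and
modulation describe a fibre's response across passive motion, walking and
running.

`vestaff` implements this full analysis chain together with a calibrated
synthetic-afferent simulator, so that every stage can be validated against
known ground truth without any recorded data.

# Models

**Linear rate models.** For a canal afferent the estimated firing rate is
regressed on pitch velocity and acceleration,
$\hat{fr}(t) = b + S_v \dot H(t) + S_a \ddot H(t)$,
and for an otolith afferent on linear acceleration and jerk,
$\hat{fr}(t) = b + S_a \ddot H(t) + S_j \dddot H(t)$,
with the bias $b$ representing the resting discharge. Fitting is restricted
to samples with rate above 10 sp/s so that segments potentially driven into
cutoff do not distort the estimate; `fit_linear_rate_model()` applies this
restriction per sample. The frequency-resolved response modulation is
$S_t = \sqrt{S_v^2 + (2\pi f S_a)^2}$ (and the acceleration/jerk analogue
for otoliths; `gain_at_frequency()`). Multicollinearity of the two motion
channels is monitored with variance inflation factors, and fits report
VAF $= 1 - \mathrm{var}(\text{resid})/\mathrm{var}(\text{obs})$.

**LN cascade.** `fit_ln_model()` composes four stages:

1. *Lag alignment.* The response lead is the shift of the head-motion
   channel maximizing its cross-correlation with the firing rate
   (search window ±50 ms, parabolic sub-sample refinement); positive lead
   means firing precedes motion and the motion signal is advanced.
2. *Linear range.* Samples with stimulus within one SD of the stimulus mean
   are treated as the linear operating range, and the linear stage
   $r(t) = S_t H(t) + r_0$ is fitted there by least squares.
3. *Static nonlinearity.* The firing rate is averaged within stimulus bins
   (0.0004 g for otolith acceleration; stimulus SD/50 for canal velocity,
   chosen to give comparable bin occupancy) and the erf sigmoid
   $T_{sig}(x) = \tfrac{c_3}{2}\left[1 + \mathrm{erf}\!\left(\tfrac{x - c_2}{\sqrt{2 c_1}}\right)\right]$
   is fitted to binned mean rate versus linear prediction by weighted
   nonlinear least squares (weights = bin counts).
4. *Prediction.* $N(t) = T_{sig}(S_t H(t) + r_0)$, bounded in $[0, c_3]$ and
   never negative, scored by VAF against the observed rate.

Response bias is the cascade's rate at zero head motion, $T_{sig}(r_0)$,
and the modulation is the slope of the sigmoid at the same operating point
through the linear stage, $S_t\,T_{sig}'(r_0)$ — this keeps the LN bias and
modulation unit-commensurate with the linear model's $b$ and gain, and in
the linear regime the two pairs agree. (The inflection-point slope is a
re-parameterization away for users who prefer it.)

**Curvature correction.** Within one stimulus SD a strongly driven afferent
is not perfectly linear, so the ordinary-least-squares linear stage is
attenuated by sigmoid curvature. For Gaussian drive through an erf
nonlinearity the attenuation is exactly
$1/\sqrt{1 + \sigma_m^2/c_1}$, where $\sigma_m$ is the masked
linear-prediction SD — both measurable from the fit itself. With
`curvature_correction = TRUE` (default) the gain is de-attenuated by this
Bussgang-type factor and the sigmoid refitted once; this is what makes
ground-truth recovery of $(S_t, c_1, c_2, c_3)$ accurate to a few percent
on strongly driven records. The correction is approximate when the masked
drive is far from Gaussian.

# Spike-train processing

**Rate estimation.** `estimate_firing_rate()` bins spikes at the stimulus
rate (default 1 kHz) and convolves with a unit-DC-gain Kaiser-window FIR
low-pass filter. The filter parameters are not dictated by the model, so
the package chooses a 25 Hz cutoff with a 10 Hz transition band and 60 dB
stop-band attenuation: flat (|H| ≈ 1) below ~15 Hz, i.e. over all
locomotor head-motion content, and fully attenuating spike harmonics. Small
negative ringing is clipped at zero; the clip is applied after the exactly
linear filtering core (`clip_negative = FALSE` exposes the unclipped
estimator). The integral of the estimated rate matches the spike count to
within ~1% for trains above ~40 sp/s; for very sparse trains clipping of
ringing inflates the integral by a few percent, a known property of any
clipped linear estimator.

**Regularity.** CV\* normalizes the ISI coefficient of variation to a
standard mean ISI of 15 ms. The classical normalization curves are not
reproduced here; instead `cv_star_calibration()` tabulates cv against mean
ISI for gamma-renewal trains across shapes 1–200, and `interspike_regularity()`
interpolates the observed (cv, mean ISI) pair along constant-shape contours
to 15 ms. For renewal trains these contours are flat (cv is mean-free), so
CV\* ≈ CV; the table (shipped as `inst/extdata/cv_star_calibration.csv`,
regenerable from code) exists so that the normalization is an explicit,
monotone, reproducible map rather than an implicit identity. Classification
uses the 0.15 cutoff; the tie CV\* = 0.15 is assigned to irregular so the
rule is deterministic. A minimum of 500 resting ISIs is required — a package
choice, configurable.

**Cutoff statistics.** `zero_rate_probability()` reports the fraction of
samples at or below 0.5 sp/s by default; the epsilon absorbs filter
ringing around true silence. Because a low-pass-filtered sparse spike train
dips toward zero between spikes, the statistic carries a rate-dependent
floor for irregular trains below ~40 sp/s; condition *contrasts* within an
afferent are therefore the meaningful quantity, as in the analysis
pipeline. `cycle_modulation()` reports the average peak-to-peak modulation
across stimulation cycles; with `folded = TRUE` cycles are averaged into
one waveform first, which suppresses spiking noise and recovers the
closed-form depth $2 S_v A$ for sinusoidal drive.

# The synthetic cohort

The simulator is the package's test bed: four afferent classes
(regular/irregular × canal/otolith) with known ground truth, each recorded
with identical parameters in every condition (the within-afferent design),
default class counts 15/17/9/14, plus a stimulus-free resting record per
fibre.

**Forward model.** Drive = coefficients applied to the stimulus advanced by
the response lead, plus $r_0$; then either hard rectification at zero
("linear-rectified") or an erf sigmoid; then inhomogeneous gamma-renewal
spiking by time rescaling (trapezoidal cumulative intensity — the
rectangular sum would shift spikes by half a sample and alias into the
derivative coefficients). The renewal shape κ sets resting regularity,
CV ≈ 1/√κ: κ = 100 (CV ≈ 0.10) for regular and κ = 16 (CV ≈ 0.25) for
irregular classes, either side of the 0.15 cutoff.

**Stimuli.** The head-motion statistics the conditions must reproduce are
fractions of samples beyond ±1.5 SD of the walking-matched passive
reference: 3% (passive against itself), 5% (walking) and 15% (running) for
net linear acceleration, and 3/2/4% for rotational pitch velocity. A pure
Gaussian process puts 13.4% beyond ±1.5 SD, so passive and walking
marginals must be *lighter*-tailed than Gaussian — consistent with
machine-generated passive profiles and with the bounded, rhythmic character
of walking — while running must combine a modest core with rare violent
bursts. The generator therefore uses:

- a band-limited Gaussian process (power ∝ $1/(1+(f/f_c)^{2q})$, $q = 4$;
  $f_c$ = 4 Hz for the walking pair, 5.5 Hz for running, giving running the
  relatively higher-frequency content seen in its flatter cumulative
  spectrum);
- for passive/walking, a monotone squash $y = \tanh(\lambda z)/\lambda$ of
  the Gaussian marginal, with λ calibrated by root-finding on the exact
  analytic tail probability for each condition's target;
- for running acceleration, a two-component Gaussian scale mixture realised
  by a slow binary envelope (corner 1 Hz, the stride-burst time scale):
  80% of time a narrow component, 20% a wide one, with the component SDs
  solved in closed form so the mixture puts exactly 15% of its mass beyond
  1.5 reference SDs at twice the walking SD. The result is strongly
  leptokurtic (kurtosis ≈ 13 at the defaults), matching the qualitative
  observation that running acceleration is both larger-SD and
  heavier-tailed.

Walking SDs default to 0.12 g (net acceleration) and 15 deg/s (pitch
velocity) — ordinary magnitudes for locomotor head motion — with running at
2× the acceleration SD and 1.1× the rotational SD. Channels are scaled to
exact sample SD so that tail thresholds are stable across records.
Sinusoidal passive conditions are exact 1 Hz sinusoids at ±0.2 g and
40 deg/s. Derivative channels (angular acceleration, jerk) are central
differences after a shared 125 Hz low-pass; the simulator and all fits use
the same derived channels, so there is no convention mismatch.

**Class parameters.** Resting discharges are drawn from 60–100 sp/s ranges
per class; canal gains 0.3–0.5 (regular) and 0.8–1.2 (irregular)
(sp/s)/(deg/s); regular otolith gains 60–100 (sp/s)/g. Irregular otolith
fibres are the high-sensitivity class: most members are rectified-linear
with gain 2.2–2.6 × $r_0$ per g — placed so that the *bounded* walking
acceleration never reaches cutoff while the unbounded running bursts do —
and 30% of members are saturating cells with erf-sigmoid ground truth
(rest at inflection, unit local gain) and gain 4.5–6 × $r_0$ per g. The
rectified members produce the cutoff signatures (elevated zero-rate
probability and mean rate above resting during running only); the
saturating members are the cutoff-regime cells whose running responses a
passive-fitted linear model fails to predict while the LN cascade recovers
them, with the VAF ratio exceeding two-fold. Canal acceleration and otolith
jerk coefficients default to small fractions of the primary gain
(10–15 ms and ~4–5 ms effective phase leads).

# Design choices on open points

- **Lead alignment before the two-channel linear fit.** A time shift τ is,
  to first order, equivalent to adding τ times the derivative channel:
  the (velocity, acceleration) and (acceleration, jerk) models *absorb*
  small leads into their derivative coefficient. Automatically shifting by
  the cross-correlation lag before a two-channel fit therefore changes the
  coefficient representation without improving the fit, and breaks exact
  recovery of constructed coefficients. `fit_linear_rate_model()` hence
  defaults to `lead = 0`, with a numeric lead or `lead = "auto"` available.
  The LN cascade, whose linear stage uses a single channel, always
  estimates and applies the lead.
- **Whether the >10 sp/s mask is recomputed after alignment:** it is
  applied after alignment, per sample.
- **Sigmoid fit on binned means versus raw pairs:** binned means weighted
  by counts by default (raw pairs available by calling `fit_sigmoid()`
  directly). Initialization: $c_3$ at the maximum smoothed binned rate,
  $c_2$ at the half-maximum crossing of a weighted running mean (narrow
  noisy bins make the raw crossing unstable), $c_1 = (\text{range}/4)^2$;
  bounds keep $c_1, c_3 > 0$; the optimizer is deterministic. If the data
  carry no sigmoidal curvature the fit falls back to a wide quasi-linear
  sigmoid matched to the local slope and operating point, flagged
  `converged = FALSE` — bias and modulation remain well-defined in that
  case even though $c_1, c_2, c_3$ individually are not identified.
- **Spectral estimation:** averaged modified periodograms (2 s Hamming
  windows, 50% overlap), written in the package because no installed
  library provides a Welch estimator; the Parseval identity is tested. The
  cumulative-spectrum area is computed on the normalized cumulative curve
  over 0–15 Hz.
- **Kurtosis convention:** Pearson (non-excess), normal = 3, stated in
  outputs.
- **Gravity extraction for mean orientation:** 0.5 Hz low-pass, pitch angle
  from the fore-aft/dorsoventral arctangent, averaged over the record.

# What the synthetic tests do and do not show

Passing the suite demonstrates that the estimators recover the generative
parameters of renewal-spiking afferents driven through static
nonlinearities, and that the analysis pipeline reproduces, end to end, the
qualitative condition-specific phenomena the generator is calibrated to:
amplitude-tail orderings across conditions, cutoff signatures confined to
the irregular-otolith class during running, and condition-invariant LN bias
and modulation when the ground truth is condition-invariant.

The generator does not emulate several features of real recordings:
adaptation and frequency-dependent (dynamic) gains, efferent modulation,
three-dimensional kinematics beyond pitch plus a scalar net acceleration,
gait-locked periodicity of locomotor head motion, or non-renewal spike
history effects. Results on real data therefore depend on assumptions the
synthetic tests cannot check — in particular the adequacy of a *static*
nonlinearity and of the single-lead alignment.

Problem sizes used in the shipped tests are the package's validation
choices: 300 s records for calibration and parameter recovery (recovery of
linear coefficients to within 5% and LN parameters to within 10% at those
lengths), 30–120 s records and reduced class counts for pipeline-level
pattern checks.

# Limitations

- CV\* normalization is self-calibrated on gamma renewal and is only an
  approximation of the classical normalization for real afferents, whose
  cv-vs-mean-ISI contours are not flat.
- The zero-rate statistic has an estimator-induced floor for sparse
  irregular trains; compare conditions within a fibre rather than absolute
  values across fibres.
- The curvature correction assumes Gaussian masked drive; for strongly
  skewed stimuli the residual gain bias can reach a few percent.
- The >10 sp/s restriction is per sample; segment-based masking with a
  minimum duration is not implemented.
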