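Package: vestaff
Title: Linear and Linear-Nonlinear Encoding Analysis of Vestibular Afferents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how vestibular afferents (semicircular-canal
    and otolith fibres) encode head motion across passive stimulation, walking
    and running. Implements firing-rate estimation from spike trains by
    Kaiser-window low-pass filtering, interspike-interval regularity (CV*)
    classification, least-squares linear rate models with velocity/acceleration
    (canal) or acceleration/jerk (otolith) regressors and VAF/VIF diagnostics,
    a linear-nonlinear (LN) cascade with an erf-sigmoid static nonlinearity
    (lag alignment, linear-range selection, stimulus binning, bias and
    modulation extraction), head-motion stimulus statistics (spectral power,
    cumulative spectra, amplitude tails, kurtosis, mean orientation), and a
    calibrated synthetic-afferent simulator (band-limited stimuli with
    controlled amplitude tails; inhomogeneous gamma-renewal spiking) providing
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
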