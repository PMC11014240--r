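Package: cwmsim
Title: Piecewise Simulation of Heartbeat-Induced Chest Wall Motion
Version: 0.1.0
Authors@R:
    person("cwmsim", "developers", email = "cwmsim@example.org", role = c("aut", "cre"))
Description: Generates realistic heartbeat-induced chest-wall displacement
    traces as observed by continuous-wave radar or infrared motion capture
    during breath-hold. A cardiac cycle is split into ten phases whose
    durations and extremal velocities are drawn from physiologically
    motivated distributions; each phase's velocity is shaped by a dedicated
    segment function (sinusoid, logistic, exponential decay, Rayleigh,
    cosine, skewed Gaussian) and rescaled onto its sampled extremes.
    Per-beat heart-rate variability, additive white Gaussian noise,
    trapezoidal integration to displacement and polynomial baseline
    removal turn the per-cycle velocities into arbitrarily long labelled
    recordings. Includes three published comparison models (van der Pol
    oscillator, Gaussian pulse train, improved Gaussian pulse) and an
    evaluation toolkit (dynamic time warping, RMSE, sliding-window
    matching, Hamming-windowed amplitude spectra).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
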