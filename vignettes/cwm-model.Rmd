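---
title: "Modelling heartbeat-induced chest wall motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heartbeat-induced chest wall motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwmsim)
```

## The problem

Continuous-wave radar and infrared motion capture can resolve the
sub-millimetre displacement of the chest surface produced by the beating
heart. Signal-processing and deep-learning work on such recordings is
starved for labelled data: collecting it needs synchronized radar, ECG and
clinical supervision, and almost no public dataset isolates the heartbeat
component. `cwmsim` generates arbitrarily large labelled datasets of
heartbeat-induced chest-wall displacement under breath-hold, with every
beat's phase boundaries and extremal velocities known exactly.

## The model

A cardiac cycle (one P-wave peak to the next) is divided into ten phases
whose boundaries are anchored to ECG landmarks: atrial systole up to the
Q-adjacent point *b*, isovolumetric contraction inside the R–S span, the
ejection complex (*c*–*J*–*e*–*f*–*g*–*t*–*h*, spanning the ST segment and
T-wave), isovolumetric relaxation into the trough *k*, and ventricular
filling back to the next cycle.

**Timing.** The cycle length is Gaussian, mean 0.82 s, sd 0.08 s, truncated
by rejection to [0.58, 1.07] s — the resting window of 56–102 bpm with
`floor(60/bpm, 2)` at the fast end. The systolic/diastolic split uses a
ratio r ~ U[0.7, 0.9] (systole = r·cycle/(1+r)); each phase then draws its
duration from a physiological range (IVC 9–13 % of systole, QRS 1.8–2.5 ×
IVC capped at 120 ms, S–J 10–30 ms, ST 70–90 ms, IVR 9–13 % of diastole,
atrial systole 16–22 % of diastole and longer than the QRS, rapid filling
25–40 % of diastole). Reduced filling takes the diastolic remainder, so the
phases conserve the cycle exactly. The T-wave length is what remains of
systole after IVC, S–J and ST.

**Velocity.** Each phase's velocity shape is a simple analytic function —
a sinusoid (atrial systole), logistic sigmoids (IVC rise, f–g rise),
exponential decays (ejection drop-offs), Rayleigh pulses (J–e recoil and
filling), a cosine (g–t), a 3π/2-shifted sine (t–h) and a skewed Gaussian
(relaxation) — evaluated on the sampled grid and affinely rescaled onto
sampled extremal velocities (e.g. the ejection trough at *J* is
−U[0.1, 0.7] × v_rpe with v_rpe ~ U[0.04, 0.14]). Under the default
`inward_negative` convention systolic extremes are negative and filling
peaks positive, so integrated displacement dips during systole and
recovers in diastole. Only the f–g → g–t junction is pinned (the cosine's
maximum is the last f–g value); other junctions are left free as in the
underlying design, and their jump magnitudes are reported in the trace
metadata.

**Long sequences.** Per-beat heart-rate variability multiplies each cycle
length by (1 + d), d ~ Normal(0, σ) with σ = |U(−0.015, 0.015)| per run and
d clipped to ±0.1. Each noisy velocity cycle is linearly resampled to its
beat interval, the cycles are concatenated, integrated with the trapezoidal
rule, detrended with a cubic least-squares fit (the unequal systolic and
diastolic areas otherwise tilt the integral) and min–max scaled to a
peak-to-peak amplitude a ~ U[0.5, 1.1] mm. White Gaussian noise is added in
the velocity domain at a configurable SNR (default 10 dB).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fs` | 100 Hz | sampling rate; 100 Hz resolves the shortest (~20 ms) segments |
| `snr_db` | 10 dB | velocity-domain white-noise level; `"none"` disables |
| `amplitude_mm` | U[0.5, 1.1] | peak-to-peak displacement of a resting heartbeat |
| `hrv_sigma_range` | [−0.015, 0.015] | per-run HRV sd draw (absolute value used) |
| `detrend_order` | 3 | polynomial order of baseline removal |

Every sampler range (Table-style timing and velocity intervals) is
overridable through the `timing:`, `velocity:` and `segments:` config
sections; overrides must stay inside the published ranges, and a scalar
override pins the draw.

## Numerical choices

* The default sampling rate was never stated by the model's source; 100 Hz
  is typical of the radar systems this emulates and is configurable.
* Logistic steepness is solved from the saturation equality
  (`1/(1+e^(−kL/2)) = 0.9` for IVC, 0.99 for f–g); the printed `1−e` form
  of the sigmoid is unusable (it exceeds 1 everywhere) and was corrected to
  the standard logistic.
* Segment boundaries are quantized to the sample grid by rounding; the
  final segment absorbs the rounding tail. A sampled layout occasionally
  quantizes a short segment (b–c, c–J, g–t, t–h can be under 20 ms) to
  fewer than 2 samples at 100 Hz, and independent velocity draws can
  produce an empty rescale interval (e.g. v_g below v_t). Both are rejected
  and the cycle redrawn, up to 1000 attempts; the operations themselves
  raise so misuse is never silent.
* Retiming to the beat interval is deterministic linear resampling;
  `retime = "random_edit"` provides the literal random deletion/duplication
  variant for users who want sample-level jitter.
* "Standard deviations within [−0.015, 0.015]" is not meaningful as a
  signed sd; the absolute value of the uniform draw is used.
* Rejection loops are bounded at 1000 draws and raise rather than clip, so
  inconsistent overrides surface as errors.
* DTW is the full O(nm) dynamic program with absolute-difference cost and
  no warping band, in C++; both windows are min–max normalized to [0, 1]
  before DTW/RMSE by default (`--no-normalize` switches this off), since
  comparable published distances presuppose normalized inputs.

## What the generator does and does not emulate

The synthetic traces reproduce: the phase-anchored velocity morphology of
breath-hold chest-wall motion, beat-to-beat pseudo-periodicity, realistic
amplitude and noise, and a harmonic spectrum whose intensity decays with
order. They do not contain respiration, body-motion artifacts, radar
phase-demodulation effects, arrhythmia, or age extremes (the ranges derive
from healthy adult data). A green test therefore establishes internal
consistency with the stated physiological ranges — not equivalence to any
individual's recording.

Two test-design consequences are worth knowing. First, the beat-length sd
of 0.08 s smears the spectral fundamental over roughly 0.1 Hz, so the
"peak within one FFT bin of 1/mean(BBI)" property is checked on a 20 s
window, where the bin width exceeds the smear; on much longer windows the
peak bin wanders inside the smear, which is physics, not a defect. Second,
a cubic detrend over a finite window absorbs a small O(1/(ωT)) fraction of
any oscillation, so detrending correctness is verified against a
regression oracle rather than by demanding the residual equal the
noise-free oscillation.

## Baseline models

For comparison parity the package ships three published alternatives: a
van der Pol relaxation oscillator (fixed-step RK4 from state (0, 1); α
defaults to 1 and ω to one oscillation per mean cycle since the source
states neither), a Gaussian pulse train (a = 0.2, c = 0.1 s, pulse times
from the same cycle-length sampler), and an improved Gaussian pulse whose
modulated acceleration is double-integrated to displacement with a linear
detrend after each pass (without it the double integral diverges). The
published constant b = 50 for the latter only makes sense on a
sample-index scale and is implemented that way, with an override.

## Worked example

```{r example, eval = FALSE}
cfg <- cwm_config(seed = 7, duration = 8, fs = 100)
tr  <- build_long_sequence(cfg)
tr
diff(range(tr$samples))          # peak-to-peak, mm
mean(tr$meta$bbi)                # mean beat interval, s
sp <- amplitude_spectrum(tr)
sp$freq_hz[which.max(sp$magnitude[sp$freq_hz > 0.5])]
```

## Known limitations

* Junction discontinuities between independently rescaled segments are
  physical in origin (the source rescales independently) but can look like
  micro-steps at high sampling rates; inspect `meta$junction_jumps`.
* Velocities are normalized model units until the final min–max amplitude
  scaling; the velocity channel written alongside displacement is therefore
  dimensionless.
* The HRV model is white (independent per beat); real beat series show
  autocorrelation and respiratory sinus arrhythmia.
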