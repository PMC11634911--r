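---
title: "Estimating left-ventricular pressure indices from heart sounds, ECG and pulse oximetry"
author: "phonopress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating left-ventricular pressure indices from heart sounds, ECG and pulse oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonopress)
```

## The problem

Left-ventricular (LV) filling pressure is central to the diagnosis and
management of heart failure: an end-diastolic pressure (EDP) above
15 mmHg at rest is a standard diagnostic cutoff, and EDP, end-systolic
pressure (ESP) and the contractility index dPdt_max (the maximum rate of
pressure rise during the systolic upstroke, mmHg/s) are all read from an
intraventricular catheter — an invasive, costly and risk-bearing
measurement. The premise of this package is that a combination of cheap,
routine, non-invasive signals — the ECG, the pulse-oximetry plethysmogram
(POX) and the phonocardiogram (MIC) — carries enough per-beat information
to regress these indices beat by beat.

`phonopress` implements the full chain: beat segmentation driven by the
heart-sound envelope, an 18-dimensional per-beat predictor set, per-step
linear model evaluation, and a four-channel simulator that generates
recordings with known per-beat truth so every stage can be validated
quantitatively.

## Beat segmentation from the MED signal

The phonocardiogram is up- and down-enveloped (default: moving
maximum/minimum over a 50 ms window, followed by a moving-average
smoothing of the same width, which guarantees `upper >= lower`
everywhere; an alternative spline-through-peaks envelope is available).
The difference of the two envelopes is the *microphone envelope
difference* (MED) signal. Band-passed around the heart-rate fundamental
(passband `[0.7, 1.3] * HR/60` Hz, 4th-order Butterworth applied
forward–backward so that minima do not shift in time), the MED becomes a
near-sinusoidal once-per-beat oscillation whose local minima approximate
the systole/diastole boundary. The boundary for each RR interval is the
deepest local minimum within `[0.2, 0.6] * RR` after the R-peak; beats
with no minimum in that window are flagged `no_med_minimum`, and beats
shorter than 250 ms are flagged `rr_too_short`. Flagged beats never reach
the regressions — the reporting stage shows them as reduced `n` or as
`not available` rows rather than guessing.

Design notes, where the procedure is genuinely open:

* *Envelope algorithm.* Sliding extrema were chosen as the default
  because they bound the signal by construction; spline interpolation
  through peaks can overshoot on sparse peaks. The window (50 ms) spans
  at least two periods of the lowest heart-sound carrier (~40 Hz).
  The moving-extrema estimator has a known worst-case bias of
  `|d envelope/dt| * window/2` at steep amplitude modulation — about 5%
  for a 1 Hz modulation — which is acceptable for boundary timing since
  the bias is symmetric in the upper and lower envelopes.
* *Band-pass width.* "Pass only the HR" is realized as ±30% around the
  fundamental: wide enough to tolerate RR jitter, narrow enough to reject
  the second harmonic. Zero-phase filtering is essential; a causal filter
  would delay the minima by tens of milliseconds.
* *Search window.* Systole occupies roughly 35–55% of the cycle across
  the pacing range (the simulator uses a Bazett-like
  `0.32 * sqrt(RR)` systole duration), so `[0.2, 0.6] * RR` brackets the
  boundary while excluding S1-related minima.
* *R-peak detection.* An energy detector (band-pass 5–30 Hz,
  differentiate, square, 120 ms integration, adaptive threshold at 0.4 ×
  a rolling 95th percentile, 240 ms refractory, peak refinement on the
  band-passed ECG) — invariant to positive rescaling of the ECG by
  construction.

## The 18 predictors

Per beat, with the systolic segment `[R, boundary)` and the diastolic
segment `[boundary, next R)`:

* **invPTT** (1): the pulse transit time is measured from the R-peak to
  the maximum first derivative of the POX within `(R, R + 0.6 RR]`; the
  predictor is its reciprocal. The POX is smoothed (25 ms moving average)
  before differentiation because the plethysmographic upstroke has a
  bandwidth of a few hertz and an unsmoothed derivative is dominated by
  sensor noise. Beats without a positive upslope are flagged
  `no_pox_upstroke`.
* **Set A** (4 per phase): spectral flux, kurtosis, skewness and slope of
  the mel spectrogram of the segment (25 ms Hann frames, 10 ms hop, 32
  triangular mel bands over 20–500 Hz, `mel = 2595 log10(1 + f/700)`).
  Moments are energy-weighted over band centers; slope is the
  least-squares slope of energy on band center; flux is the Euclidean
  norm of the difference of unit-sum-normalized consecutive frames. Each
  feature is the arithmetic mean over frames. Frames with zero energy or
  zero spread are skipped; a fully degenerate phase is flagged
  `degenerate_spectrum`.
* **Set B** (13 per phase): delta-delta MFCCs — orthonormal DCT-II of
  `log(energy + 1e-10)`, coefficients 0–12, second regression delta
  (window 2, edge frames replicated), averaged over frames. An offset
  switch selects coefficients 1–13 instead, since conventions differ.

Scale behavior is deliberate and tested: kurtosis, skewness, flux and the
delta-delta MFCCs are invariant to a positive gain on the MIC (the log
turns gain into an additive constant that the delta operator removes),
while slope scales linearly with power gain — so exactly one feature
retains absolute loudness.

The prediction strategy pairs phases with targets: systolic sounds
predict the *preceding* EDP (the filling pressure just before that
contraction) and the *contemporary* dPdt_max; diastolic sounds predict
the *preceding* ESP. Every target therefore sees exactly 18 predictors:
invPTT + 4 set A + 13 set B of its phase.

## Regression and reporting

Per pacing step and target, two nested ordinary-least-squares fits are
compared: `invPTT` alone versus all 18 predictors. Predictors are
standardized internally for conditioning only; coefficients are reported
on the original scale. Reported metrics:

* `r_squared`: in-sample coefficient of determination. Because the models
  are nested and evaluated in-sample, R²(full) ≥ R²(invPTT) must hold
  exactly; the fitting stage asserts it on every run.
* `rmse`: the residual standard error `sqrt(SSres / (n - p - 1))`. The
  degrees-of-freedom correction is the default because it is the only
  convention under which a richer model can show a *higher* RMSE together
  with a higher R², a pattern that occurs in practice when 17 extra
  predictors buy little variance; a plain `sqrt(SSres / n)` variant is
  one flag away.
* 95% bounds: pointwise mean-prediction confidence bounds of the
  regression of the response on the fitted linear combination (the
  "whole model" axis), on a 100-point grid; prediction intervals are
  available by flag. Mean-prediction bounds are the default because the
  bounds annotate the fitted line, not future beats.
* `not_available`: emitted for rank deficiency, `n < p + 2`, or an
  upstream stage failure, with the reason; high pacing rates with few
  valid beats produce exactly this pattern.

In-sample evaluation (no train/test split) is the default because the
scientific claim being evaluated is per-step linear decodability, not
out-of-sample generalization; a k-fold option would be a natural
extension but is out of scope here.

## The simulator

`simulate_hemodynamics()` draws, per step of the pacing protocol
(spontaneous ≈78, 100, 120, 140, 160 beats/min; ≥3-minute steps), beat
times with 2% multiplicative RR jitter and per-beat EDP/ESP/dPdt_max as
stationary AR(1) chains (relative σ = 0.05, ρ = 0.5) around the preset
means. Two presets reproduce the baseline hemodynamics of a healthy and
a tachypacing-induced HFrEF animal (EDP 5.70 / 15.45 mmHg, ESP
64.81 / 77.65 mmHg, dPdt_max 1168.75 / 581.55 mmHg/s, HR 78). The pulse
transit time is `0.15 s − 0.0015 s/mmHg × (ESP − mean ESP)`, floored at
50 ms — the negative coupling that makes invPTT a blood-pressure
predictor.

`render_signals()` turns the truth into four channels at 1 kHz:

* **ECG**: Gaussian QRS at each R time (σ = 8 ms) plus P and T bumps.
* **LVP**: per beat, a raised-cosine upstroke whose peak slope equals
  dPdt_max exactly, a raised-cosine ejection decay through ESP at the
  end-systole time, a 5 ms isovolumic shoulder, and an exponential
  relaxation linearly corrected to land on the next beat's EDP. The
  shoulder makes the minimum of dP/dt fall at the start of relaxation,
  where pressure is still within a few percent of ESP — matching the
  standard end-systole surrogate used on the extraction side.
* **MIC**: S1 at systole onset (carrier 40 Hz) and S2 at end-systole
  (65 Hz), raised-cosine-enveloped sinusoid bursts whose gain and carrier
  frequency are affine in the indices: S1 gain ↑ with dPdt_max, S1
  frequency ↑ with EDP, S2 gain and frequency ↑ with ESP. The HFrEF
  preset renders louder sounds than the healthy one. A third, diastolic
  filling sound (an S3/S4-type gallop, 45 Hz) is placed per beat with
  amplitude and timing solved in closed form so that the fundamental of
  the MED bump train points half a cycle away from the systole/diastole
  boundary — i.e. the band-passed MED attains its per-cycle minimum at
  the boundary. This is not a numerical convenience but the physical
  requirement for MED-minima segmentation to work at all: with acoustic
  energy only at S1 and S2 (both in the first half of the cycle), the
  fundamental's minimum necessarily falls in mid-diastole, far from
  end-systole. Loud HFrEF hearts with gallop sounds are exactly the
  setting in which envelope minima line up with the LVP peaks; the
  simulator makes that mechanism explicit and controllable
  (`coupling_config(diastolic_sound = FALSE)` restores a silent
  diastole, under which the segmentation property is *expected* to fail).
* **POX**: one self-contained raised-cosine pulse per beat whose maximum
  upslope lags the R time by exactly that beat's PTT (evaluated on the
  exact sample grid, so the fiducial is sample-accurate), with amplitude
  tied to pulse pressure.

White Gaussian noise is added per channel at a configurable SNR relative
to the channel's AC power. The scalar form applies to the non-invasive
channels; the invasive LVP reference keeps a separate 60 dB default,
since it plays the role of the gold-standard measurement whose indices
the models are fitted against.

### Calibration of the acoustic coupling

The coupling coefficients (burst duration 120 ms; S1 gain coefficient
2.0 on relative dPdt_max; S1 frequency coefficient 3.0 on relative EDP;
S2 gain/frequency coefficients 1.5/1.5 on relative ESP) were chosen once,
as part of the simulator's design, so that the features linearly encode
the indices strongly enough for (a) noise-free full-model fits to reach
R² ≥ 0.99 for all three targets and (b) the EDP fit to stay near R² 0.8
at 20 dB MIC noise with ~150 beats — i.e. so that the simulator defines a
testbed on which the pipeline's recovery can be meaningfully graded.
Bursts of 60–80 ms would be slightly more typical of S1/S2, but leave so
many silent systolic frames that the frequency-coded EDP information
falls under the 20 dB noise floor; 120 ms bursts (common in gallop-rich,
failing hearts) restore the margin. All of these are exposed in
`coupling_config()` and none is consulted by the analysis side.

## What the synthetic data do and do not show

The simulator emulates: the pacing protocol, realistic index magnitudes
and beat-to-beat autocorrelation, pressure-coupled transit times,
index-coded heart-sound spectra, gallop physiology, and broadband sensor
noise. It does not emulate: respiration and baseline wander, ectopy and
arrhythmia, valve pathology (murmurs), probe-contact artifacts,
nonstationary hemodynamic drift (except as injected in tests), or the
nonlinear and partly unknown acoustic coupling of a real thorax. Passing
the package's tests therefore demonstrates that the *pipeline* is
correct and recovers what the signals encode — it does not by itself
validate the clinical claim on real animals or patients, whose recordings
are not distributable with this package. The shipped table of published
per-step R²/RMSE reference values (`published_reference_results()`) is
included for comparison and reporting only and is never asserted as a
simulation outcome.

## Numerical choices and degenerate inputs

* Zero-phase filtering throughout (`signal::filtfilt`); filter orders as
  documented per stage.
* The log floor `1e-10` prevents `-Inf` cepstra on silent bands; the
  delta operator uses edge replication, so a single-frame segment yields
  exactly zero deltas rather than an error.
* Segments shorter than one 25 ms frame are analyzed as a single
  zero-padded frame.
* EDF files quantize to 16-bit integers: round trips are exact only to
  one quantization step (channel range / 2^16). CSV round trips are
  exact to double precision as printed (17 significant digits).
* Ties for the deepest MED minimum resolve to the earliest sample;
  plateau minima resolve to the plateau's end by slope-sign propagation.
* All randomness flows from explicit integer seeds; the RNG state of the
  caller is saved and restored, and identical seeds give bit-identical
  simulations, features and fits.

## Problem sizes used by the test-suite and the acceptance script

Tests run the simulator at 40–120 s per step (50–230 beats per step, and
~580 beats across a five-step protocol) — large enough that the
segmentation and recovery rates are estimated on hundreds of beats, and
small enough that the whole suite completes in about a minute of CPU.
The acceptance script uses 45–150 s single steps and a 60 s five-step
protocol per noise condition. These are the package's chosen test
conditions; the simulator itself defaults to the full 180 s steps of the
underlying protocol.

## Known limitations

* The MED-minima boundary is a timing *approximation*; its accuracy is
  certified only under the simulator's acoustic model (typically within
  10–20 ms, >95% of beats within 30 ms).
* In-sample R² on ~100–500 beats with 18 correlated predictors is an
  optimistic estimate of decodability; the k-fold flag exists for
  stricter use.
* The EDF writer emits a single data record per file, which standard
  readers accept but which is unusual for very long recordings.
* No arrhythmia handling beyond validity flags; a run of ectopic beats
  will simply shrink `n` and eventually produce `not available` rows.
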