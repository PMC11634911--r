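# phonopress

Non-invasive estimation of left-ventricular (LV) pressure indices from
signals a clinician can record at the bedside: the ECG, the pulse-oximetry
plethysmogram (POX) and the phonocardiogram (MIC, heart sounds).

Elevated LV filling pressure is central to diagnosing heart failure
(end-diastolic pressure, EDP > 15 mmHg at rest is a standard cutoff), but
EDP — along with end-systolic pressure (ESP) and the contractility index
dPdt_max, the maximum rate of pressure rise — can only be measured reliably
by cardiac catheterization. `phonopress` implements a per-heartbeat
regression pipeline that predicts these invasive indices from non-invasive
signals, together with a synthetic four-channel cardiac signal simulator
that provides per-beat ground truth, so the whole pipeline can be built,
validated and stress-tested without animal or patient recordings.

## The method

For a synchronized recording (ECG [V], MIC [mmHg], POX [mmHg], optionally
the invasive LV pressure LVP [mmHg], all at a nominal 1 kHz):

1. **Segmentation from the MED signal.** R-peaks and heart rate (HR) come
   from the ECG. The MIC is up- and down-enveloped; the difference of the
   envelopes is the *microphone envelope difference* (MED) signal. After a
   zero-phase band-pass that keeps only the HR fundamental, the local
   minima of the MED approximate the systole/diastole boundary of each
   beat — no pressure signal needed.
2. **Per-beat predictors (18 in total).**
   - `invPTT`: the reciprocal pulse transit time from each R-peak to the
     steepest POX upstroke (PTT correlates negatively with systolic
     pressure);
   - set A (4): spectral flux, kurtosis, skewness and slope of the mel
     spectrum of the heart sounds;
   - set B (13): the 13 mel-frequency cepstral coefficients in second
     temporal derivative (delta-delta MFCCs).
   Sets A and B are computed separately on the systolic and the diastolic
   sound segment of every beat.
3. **Per-step regression.** For each pacing step, ordinary least squares
   predicts each index from the beat-wise features: systolic sounds predict
   the preceding EDP and the contemporary dPdt_max; diastolic sounds
   predict the preceding ESP. Each index is fitted twice — from `invPTT`
   alone and from all 18 predictors (`set AB + invPTT`) — and reported as
   in-sample R² and RMSE (residual standard error), with 95% confidence
   bounds along the fitted "whole model" axis. Rank-deficient or
   under-determined fits are reported as `not available`, never silently
   dropped.

The simulator (`simulate_recording()`) emulates the study conditions this
pipeline targets: a 5-step pacing protocol (spontaneous ≈78, 100, 120, 140,
160 beats/min, ≥3 min per step), healthy and HFrEF hemodynamic presets
(e.g. EDP 5.70 vs 15.45 mmHg), AR(1) beat-to-beat variability, heart-sound
bursts whose gain and carrier frequency encode the pressure indices, and a
POX pulse delayed from each R-peak by a pressure-coupled transit time.

## Worked example

```r
library(phonopress)

sim <- simulate_recording(default_protocol(step_duration = 60),
                          hemodynamic_preset("hfref"),
                          noise = noise_config(20), seed = 7)
res <- evaluate_protocol(sim$records)
head(as.data.frame(res)[, c("step_label", "target", "predictor_set",
                            "n_beats", "r_squared", "rmse")], 6)
```

```
   step_label   target     predictor_set n_beats r_squared   rmse
1 spontaneous      EDP            invPTT      75   0.02057  0.597
2 spontaneous      EDP setAB_plus_invPTT      75   0.82753  0.286
3 spontaneous      ESP            invPTT      75   0.49678  2.877
4 spontaneous      ESP setAB_plus_invPTT      75   0.72207  2.441
5 spontaneous dPdt_max            invPTT      75   0.00467 35.974
6 spontaneous dPdt_max setAB_plus_invPTT      75   0.97405  6.632
```

Each row is one fit on one pacing step: `n_beats` heartbeats entered the
regression; `r_squared` is the in-sample coefficient of determination and
`rmse` the residual standard error in the units of the target (mmHg, or
mmHg/s for dPdt_max). At 20 dB sensor noise the full 18-feature model
explains 83% of the beat-to-beat EDP variance (RMSE 0.29 mmHg — about 2%
of the 15.45 mmHg HFrEF baseline), while `invPTT` alone explains almost
none of it: the acoustic features carry the filling-pressure information.
Because the models are nested and evaluated in-sample, R²(set AB + invPTT)
≥ R²(invPTT) holds in every successful fit. `report_summary(res)` renders
the same numbers as per-step markdown tables, and `run_pipeline()` runs
simulation → segmentation → features → indices → fits end-to-end, writing
CSV/JSON tables, a log and a seed-stamped manifest.

A thin command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/phonopress.R", package="phonopress"))') \
    run --config config.yaml --out run_dir
```

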