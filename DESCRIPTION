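Package: phonopress
Title: Non-Invasive Prediction of Left-Ventricular Pressure Indices from
    ECG, Pulse Oximetry and Heart Sounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating invasively measured left-ventricular
    pressure indices (end-diastolic pressure, end-systolic pressure and the
    maximum rate of pressure rise) from synchronized non-invasive signals:
    ECG, pulse-oximetry plethysmogram and the phonocardiogram. Implements
    heartbeat segmentation from the microphone envelope difference (MED)
    signal, per-beat time and frequency predictors (inverse pulse transit
    time, mel-spectral shape descriptors and delta-delta mel-frequency
    cepstral coefficients), per-pacing-step linear-regression evaluation
    with nested-model comparison, and a synthetic four-channel cardiac
    signal simulator with per-beat ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    zoo,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
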