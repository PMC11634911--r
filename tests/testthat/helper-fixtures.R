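# Shared simulation fixtures, built once per test run and memoized so the
# heavier acceptance checks can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# One spontaneous-rate HFrEF step, noise off; workhorse fixture.
sim_spont_clean <- function(duration = 60) {
  memo(sprintf("spont_clean_%d", duration), {
    simulate_recording(
      protocol_spec("spontaneous", 78, duration),
      hemodynamic_preset("hfref"),
      noise = noise_config(Inf),
      seed = 42
    )
  })
}

# Full five-step protocol (spontaneous 80 like the study animals), noise
# configurable.
sim_protocol <- function(snr = Inf, duration = 40, seed = 42) {
  memo(sprintf("protocol_%s_%d_%d", snr, duration, seed), {
    simulate_recording(
      default_protocol(spontaneous_hr = 80, step_duration = duration),
      hemodynamic_preset("hfref"),
      noise = noise_config(snr),
      seed = seed
    )
  })
}

# Map detected beats onto ground-truth beats by R-time proximity.
match_beats <- function(onsets_s, truth_step) {
  vapply(onsets_s, function(o) which.min(abs(truth_step$r_time - o)),
         integer(1))
}

# Boundary-recovery fraction for one step (beats whose detected
# systole/diastole boundary is within tol_ms of the true end-systole time).
boundary_recovery <- function(record, truth_step, tol_ms = 30) {
  fs <- record$sampling_rate
  sr <- segment_record(record)
  b <- sr$segmentation$beats
  idx <- match_beats((b$onset - 1) / fs, truth_step)
  err <- abs((b$boundary - 1) / fs - truth_step$end_systole_time[idx]) * 1000
  mean(b$valid & !is.na(err) & err <= tol_ms)
}

# R-peak recovery for one step: fraction of true beats matched within
# tol_ms, with no extra detections.
rpeak_recovery <- function(record, truth_step, tol_ms = 10) {
  fs <- record$sampling_rate
  rp <- detect_r_peaks(record$channels$ECG, fs)
  rp_t <- (rp - 1) / fs
  hit <- vapply(truth_step$r_time,
                function(r) any(abs(rp_t - r) <= tol_ms / 1000), logical(1))
  extras <- vapply(rp_t, function(t) all(abs(truth_step$r_time - t) >
                                           tol_ms / 1000), logical(1))
  list(recall = mean(hit), extras = sum(extras))
}

# Segmented + feature-extracted + index-extracted spontaneous step.
sim_step_features <- function() {
  memo("step_features", {
    sim <- sim_spont_clean()
    rec <- sim$records[[1]]
    sr <- segment_record(rec)
    ft <- assemble_feature_table(sr$segmentation, rec$channels$MIC,
                                 rec$channels$POX, rec$sampling_rate)
    ix <- extract_pressure_indices(rec$channels$LVP, sr$segmentation,
                                   rec$sampling_rate)
    list(table = ft, indices = ix, seg = sr$segmentation, record = rec,
         truth = sim$truth)
  })
}

# Regression tables over the whole protocol, clean and at 20 dB SNR.
protocol_results <- function() {
  memo("protocol_results", evaluate_protocol(sim_protocol(Inf)$records))
}

protocol_results_noisy <- function() {
  memo("protocol_results_noisy", evaluate_protocol(sim_protocol(20)$records))
}

# Single spontaneous-step evaluations used by the linear-decodability checks.
noisefree_spont_eval <- function() {
  memo("noisefree_spont_eval", {
    sim <- simulate_recording(protocol_spec("spontaneous", 78, 90),
                              hemodynamic_preset("hfref"),
                              noise = noise_config(Inf), seed = 42)
    as.data.frame(evaluate_step(sim$records[[1]]))
  })
}

noisy_spont_eval <- function() {
  memo("noisy_spont_eval", {
    sim <- simulate_recording(protocol_spec("spontaneous", 78, 120),
                              hemodynamic_preset("hfref"),
                              noise = noise_config(20), seed = 42)
    as.data.frame(evaluate_step(sim$records[[1]]))
  })
}
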