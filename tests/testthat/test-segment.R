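test_that("R-peak detection recovers simulated beats and is scale invariant", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  tb <- sim$truth
  fs <- rec$sampling_rate
  rp <- detect_r_peaks(rec$channels$ECG, fs)
  rr <- rpeak_recovery(rec, tb, tol_ms = 10)
  expect_equal(rr$recall, 1)
  expect_equal(rr$extras, 0L)
  expect_identical(detect_r_peaks(rec$channels$ECG * 3.7, fs), rp)
  expect_warning(out <- detect_r_peaks(rep(0, 3000), fs), "constant")
  expect_length(out, 0L)
})

test_that("heart rate is the reciprocal median RR", {
  expect_equal(estimate_hr(c(1, 751, 1501, 2251), 1000), 80)
  expect_error(estimate_hr(c(1, 751), 1000),
               class = "phonopress_insufficient_data_error")
  # paced 160 bpm with 2% RR jitter stays within 2 bpm
  sim <- sim_protocol()
  rec <- sim$records[["160bpm"]]
  rp <- detect_r_peaks(rec$channels$ECG, rec$sampling_rate)
  expect_lt(abs(estimate_hr(rp, rec$sampling_rate) - 160), 2)
})

test_that("stable-segment selection keeps stationary data, drops drift", {
  # low beat-to-beat variability so every per-beat proxy sits well inside
  # the +/-10% band; the test isolates the windowing rule itself
  sim <- simulate_recording(protocol_spec("spontaneous", 78, 60),
                            hemodynamic_preset("hfref"),
                            coupling_config(sigma = 0.02),
                            noise = noise_config(Inf), seed = 12)
  rec <- sim$records[[1]]
  fs <- rec$sampling_rate
  rp <- detect_r_peaks(rec$channels$ECG, fs)
  win <- select_stable_segment(rec, rp, min_duration = 30)
  expect_equal(win$start, rp[1])
  expect_equal(win$end, rp[length(rp)] - 1L)

  # inject a +25% LVP drift into the middle third: the selected window may
  # reach into the early ramp (still within +/-10% of its median) but must
  # exclude the upper part of the drift
  rec2 <- rec
  n <- record_length(rec2)
  mid <- seq(round(n / 3), round(2 * n / 3))
  ramp <- seq(0, 0.25, length.out = length(mid))
  rec2$channels$LVP[mid] <- rec2$channels$LVP[mid] * (1 + ramp)
  win2 <- select_stable_segment(rec2, rp, min_duration = 10)
  high_drift <- mid[ramp > 0.22]
  expect_true(win2$end < min(high_drift) ||
                win2$start > max(high_drift))

  expect_error(select_stable_segment(rec, rp, min_duration = 180),
               class = "phonopress_no_stable_segment_error")
})

test_that("sliding-extrema envelopes recover analytic amplitudes", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 40 * t)
  env <- compute_envelopes(x, fs)
  core <- seq(round(0.1 * fs), length(t) - round(0.1 * fs))
  expect_lt(max(abs(env$upper[core] - 1)), 0.02)
  expect_lt(max(abs(env$lower[core] + 1)), 0.02)

  envc <- compute_envelopes(rep(3.2, 500), fs)
  expect_lt(max(abs(envc$upper - 3.2)), 1e-12)
  expect_lt(max(abs(envc$lower - 3.2)), 1e-12)

  # 1 Hz amplitude modulation: MED tracks twice the modulation envelope.
  # The moving-extrema window (50 ms) looks ahead/behind by half its
  # width, so the estimator's worst-case bias at the modulation's steepest
  # slope is ~|d env|*w/2 (~5% here); typical error is far smaller.
  am <- (1 + 0.5 * sin(2 * pi * 1 * t)) * sin(2 * pi * 40 * t)
  env2 <- compute_envelopes(am, fs)
  med <- env2$upper - env2$lower
  expected <- 2 * (1 + 0.5 * sin(2 * pi * 1 * t))
  rel <- abs(med[core] / expected[core] - 1)
  expect_lt(stats::quantile(rel, 0.95, names = FALSE), 0.05)
  expect_lt(max(rel), 0.06)

  expect_error(compute_envelopes(x, fs, window = 0.002),
               class = "phonopress_validation_error")
})

test_that("spline-peak envelopes are available and track a pure tone", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 40 * t)
  env <- compute_envelopes(x, fs, method = "spline_peaks", window = 0.02)
  core <- seq(round(0.1 * fs), length(t) - round(0.1 * fs))
  expect_lt(max(abs(env$upper[core] - 1)), 0.05)
})

test_that("the MED band-pass passes the HR fundamental and rejects 3x", {
  fs <- 1000
  hr <- 78
  f0 <- hr / 60
  t <- seq(0, 60, by = 1 / fs)
  core <- seq(round(5 * fs), length(t) - round(5 * fs))
  gain_at <- function(f) {
    med <- compute_med(sin(2 * pi * f * t), -sin(2 * pi * f * t), hr, fs)
    max(abs(med$med_filtered[core])) / 2
  }
  expect_gte(gain_at(f0), 0.9)
  expect_lte(gain_at(3 * f0), 0.1)

  upper <- sin(2 * pi * f0 * t)
  med0 <- compute_med(upper, upper, hr, fs)
  expect_lt(max(abs(med0$med_filtered)), 1e-12)
  expect_error(compute_med(upper, upper, hr = 50000, sampling_rate = fs),
               class = "phonopress_validation_error")
})

test_that("MED is nonnegative for sliding-extrema envelopes", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  env <- compute_envelopes(rec$channels$MIC, rec$sampling_rate)
  expect_true(all(env$upper - env$lower >= 0))
})

test_that("beat segmentation recovers the systole/diastole boundary", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  expect_gte(boundary_recovery(rec, sim$truth), 0.95)
  # structure: one beat per RR interval
  sr <- segment_record(rec)
  expect_equal(nrow(sr$segmentation$beats),
               length(sr$segmentation$r_peaks) - 1L)
  expect_true(all(with(sr$segmentation$beats[sr$segmentation$beats$valid, ],
                       onset < boundary & boundary < end)))
})

test_that("boundaries are invariant to positive rescaling of the MIC", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  rec2 <- rec
  rec2$channels$MIC <- rec2$channels$MIC * 12.5
  s1 <- segment_record(rec)$segmentation$beats
  s2 <- segment_record(rec2)$segmentation$beats
  expect_identical(s1$boundary, s2$boundary)
})

test_that("degenerate MED flags every beat instead of guessing", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  fs <- rec$sampling_rate
  rp <- detect_r_peaks(rec$channels$ECG, fs)
  med <- compute_med(rep(1, record_length(rec)), rep(1, record_length(rec)),
                     78, fs)
  seg <- segment_beats(med, rp, fs)
  expect_true(all(!seg$beats$valid))
  expect_true(all(seg$beats$reason == "no_med_minimum"))
  expect_error(segment_beats(med, rp[1], fs),
               class = "phonopress_insufficient_data_error")
})
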