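test_that("the default pacing protocol has the five study steps", {
  p <- default_protocol(78, 180)
  expect_equal(nrow(p), 5L)
  expect_equal(p$pacing_rate, c(78, 100, 120, 140, 160))
  expect_equal(p$label[1], "spontaneous")
  expect_error(default_protocol(78, 5), class = "phonopress_validation_error")
  expect_error(default_protocol(300, 180))
})

test_that("hemodynamic presets carry the reference baselines", {
  h <- hemodynamic_preset("healthy")
  f <- hemodynamic_preset("hfref")
  expect_equal(h$mean_edp, 5.70)
  expect_equal(f$mean_edp, 15.45)
  expect_equal(f$mean_dpdtmax, 581.55)
  expect_gt(h$mean_esp, h$mean_edp)
  expect_error(hemodynamic_preset("custom", mean_edp = 50, mean_esp = 40))
})

test_that("hemodynamic simulation is deterministic and honors sigma = 0", {
  proto <- protocol_spec("spontaneous", 78, 30)
  cc0 <- coupling_config(sigma = 0)
  t1 <- simulate_hemodynamics(proto, hemodynamic_preset("hfref"), cc0,
                              seed = 5)
  expect_true(all(t1$edp == 15.45))
  expect_true(all(t1$esp == 77.65))
  t2 <- simulate_hemodynamics(proto, hemodynamic_preset("hfref"), cc0,
                              seed = 5)
  expect_identical(t1, t2)
  expect_error(coupling_config(rho = 1), class = "phonopress_validation_error")
  expect_error(coupling_config(ptt_slope = 0.01))
})

test_that("AR(1) perturbations reproduce their stated moments", {
  # ~500 beats: sample mean within 2% of preset mean, lag-1 autocorrelation
  # within 0.1 of rho
  proto <- protocol_spec("x", 120, 260)
  tr <- simulate_hemodynamics(proto, hemodynamic_preset("hfref"),
                              coupling_config(sigma = 0.05, rho = 0.5),
                              seed = 7)
  expect_gte(nrow(tr), 480)
  expect_lt(abs(mean(tr$edp) / 15.45 - 1), 0.02)
  ac <- stats::acf(tr$edp, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac - 0.5), 0.1)
})

test_that("ground truth respects its structural invariants", {
  sim <- sim_protocol()
  tr <- sim$truth
  for (step in unique(tr$step_label)) {
    tb <- tr[tr$step_label == step, ]
    expect_true(all(diff(tb$r_time) > 0))
    expect_true(all(tb$end_systole_time > tb$r_time))
    expect_true(all(head(tb$end_systole_time, -1) < tb$r_time[-1]))
    expect_true(all(tb$esp > tb$edp))
    expect_true(all(tb$ptt > 0 & tb$ptt < 0.6 * tb$rr))
  }
  # spontaneous-step beat count matches the pacing rate within 10%
  n_sp <- sum(tr$step_label == "spontaneous")
  dur <- attr(tr, "protocol")$duration[1]
  expect_gt(n_sp, dur * 80 / 60 * 0.9)
  expect_lt(n_sp, dur * 80 / 60 * 1.1)
})

test_that("rendered LVP hits EDP, ESP and dPdt_max by construction", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  tb <- sim$truth
  fs <- rec$sampling_rate
  lvp <- rec$channels$LVP
  r_idx <- round(tb$r_time * fs) + 1
  expect_true(all(abs(lvp[r_idx] / tb$edp - 1) < 0.01))
  es_idx <- round(tb$end_systole_time * fs) + 1
  expect_true(all(abs(lvp[es_idx] / tb$esp - 1) < 0.02))
  # finite-difference max slope per beat within 2% of truth
  d <- diff(lvp) * fs
  slope_err <- vapply(seq_len(nrow(tb) - 1), function(i) {
    seg <- d[(r_idx[i]):(es_idx[i])]
    max(seg) / tb$dpdtmax[i] - 1
  }, numeric(1))
  expect_true(all(abs(slope_err) < 0.02))
})

test_that("without the gallop the phonocardiogram is silent in diastole", {
  proto <- protocol_spec("spontaneous", 78, 20)
  cc <- coupling_config(diastolic_sound = FALSE)
  sim <- simulate_recording(proto, hemodynamic_preset("hfref"), cc,
                            noise = noise_config(Inf), seed = 9)
  rec <- sim$records[[1]]
  tb <- sim$truth
  fs <- rec$sampling_rate
  mic <- rec$channels$MIC
  for (i in seq_len(nrow(tb) - 1)) {
    lo <- round((tb$end_systole_time[i] + 0.15 +
                   attr(tb, "coupling")$burst_duration) * fs)
    hi <- round((tb$r_time[i + 1] - 0.05) * fs)
    if (hi > lo) expect_lt(max(abs(mic[lo:hi])), 1e-12)
  }
})

test_that("the POX upstroke lags each R wave by exactly the beat's PTT", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  tb <- sim$truth
  fs <- rec$sampling_rate
  r_idx <- round(tb$r_time * fs) + 1
  iptt <- compute_invptt(r_idx, rec$channels$POX, fs)
  err <- abs(iptt$ptt - tb$ptt[seq_len(nrow(iptt))])
  expect_true(all(err <= 1.5 / fs))
})

test_that("PTT correlates negatively with ESP as configured", {
  sim <- sim_protocol()
  tr <- sim$truth
  expect_gte(nrow(tr), 200)
  expect_lt(stats::cor(tr$ptt, tr$esp), 0)
})

test_that("rendering is deterministic under a fixed seed", {
  proto <- protocol_spec("spontaneous", 78, 15)
  s1 <- simulate_recording(proto, seed = 3)
  s2 <- simulate_recording(proto, seed = 3)
  expect_identical(s1$records[[1]]$channels, s2$records[[1]]$channels)
  s3 <- simulate_recording(proto, seed = 4)
  expect_false(identical(s1$records[[1]]$channels$MIC,
                         s3$records[[1]]$channels$MIC))
})
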