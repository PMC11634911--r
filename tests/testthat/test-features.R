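fake_spec <- function(energies, centers = seq(50, 450,
                                              length.out = ncol(energies))) {
  structure(list(energies = energies, band_centers = centers,
                 frame_times = seq_len(nrow(energies)) * 0.01,
                 frame = 0.025, hop = 0.01),
            class = "mel_spectrogram")
}

# ---------------------------------------------------------------------------

test_that("mel spectrogram has the documented frame geometry", {
  x <- sin(2 * pi * 60 * seq(0, 0.299, by = 1e-3))
  sp <- mel_spectrogram(x, 1000)
  expect_equal(nrow(sp$energies), 28L)
  expect_equal(ncol(sp$energies), 32L)
  expect_true(all(sp$energies >= 0))
  expect_true(all(diff(sp$band_centers) > 0))

  # shorter than one frame: single zero-padded frame
  sp2 <- mel_spectrogram(rep(0.5, 10), 1000)
  expect_equal(nrow(sp2$energies), 1L)

  sp0 <- mel_spectrogram(rep(0, 300), 1000)
  expect_true(all(sp0$energies == 0))

  expect_error(mel_spectrogram(x, 800, spectro_config(fmax = 500)),
               class = "phonopress_validation_error")
})

test_that("a pure tone at a band center dominates that band", {
  fs <- 4000
  cfg <- spectro_config(frame = 0.064, hop = 0.032)
  probe <- mel_spectrogram(stats::rnorm(512), fs, cfg)
  for (k in c(15L, 22L, 28L)) {
    f_k <- probe$band_centers[k]
    tone <- sin(2 * pi * f_k * seq(0, 0.5, by = 1 / fs))
    sp <- mel_spectrogram(tone, fs, cfg)
    expect_true(all(apply(sp$energies, 1, which.max) == k))
  }
})

test_that("set A matches a brute-force moment/regression oracle", {
  withr::with_seed(11, {
    e <- matrix(stats::runif(40, 0.1, 2), nrow = 5, ncol = 8)
  })
  sp <- fake_spec(e)
  got <- spectral_features_set_a(sp)
  want <- oracle_set_a(e, sp$band_centers)
  for (nm in c("flux", "kurtosis", "skewness", "slope")) {
    expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
  }
})

test_that("set A reproduces closed-form special cases", {
  e <- matrix(0, nrow = 3, ncol = 8)
  e[, 3] <- 1; e[, 6] <- 1          # equal mass at two bands
  got <- spectral_features_set_a(fake_spec(e))
  expect_equal(got$skewness, 0, tolerance = 1e-12)
  expect_equal(got$kurtosis, 1, tolerance = 1e-12)
  expect_equal(got$flux, 0, tolerance = 1e-12)   # identical frames

  flat <- matrix(2.5, nrow = 2, ncol = 8)
  gotf <- spectral_features_set_a(fake_spec(flat))
  expect_equal(gotf$slope, 0, tolerance = 1e-12)
  expect_equal(gotf$skewness, 0, tolerance = 1e-12)  # symmetric spectrum
  # all-degenerate spectrum is flagged, not guessed
  zero <- matrix(0, nrow = 2, ncol = 8)
  gotz <- spectral_features_set_a(fake_spec(zero))
  expect_false(gotz$valid)
  expect_equal(gotz$reason, "degenerate_spectrum")
})

test_that("delta-delta MFCCs match an independent DCT+delta oracle", {
  withr::with_seed(13, {
    e <- matrix(stats::runif(7 * 32, 0.01, 5), nrow = 7, ncol = 32)
  })
  got <- mfcc_delta_delta(fake_spec(e))
  expect_length(got, 13L)
  expect_equal(got, oracle_mfcc_dd(e), tolerance = 1e-8,
               ignore_attr = TRUE)

  const <- matrix(rep(stats::runif(32, 0.5, 2), each = 4), nrow = 4)
  expect_equal(mfcc_delta_delta(fake_spec(const)), rep(0, 13),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("feature scale behavior under MIC gain is as documented", {
  withr::with_seed(17, {
    e <- matrix(stats::runif(6 * 16, 0.1, 3), nrow = 6, ncol = 16)
  })
  a1 <- spectral_features_set_a(fake_spec(e))
  a2 <- spectral_features_set_a(fake_spec(e * 4))   # power gain c^2 = 4
  expect_equal(a1$flux, a2$flux, tolerance = 1e-12)
  expect_equal(a1$kurtosis, a2$kurtosis, tolerance = 1e-12)
  expect_equal(a1$skewness, a2$skewness, tolerance = 1e-12)
  expect_equal(a2$slope, 4 * a1$slope, tolerance = 1e-12)
  d1 <- mfcc_delta_delta(fake_spec(e))
  d2 <- mfcc_delta_delta(fake_spec(e * 4))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("invPTT is the reciprocal transit time with flagged failures", {
  fs <- 1000
  # synthetic POX: single clean upstroke 200 ms after the R-peak
  r <- c(1001L, 2001L, 3001L)
  pox <- rep(0, 4000)
  for (rr in r) {
    up <- seq(0, 0.08, by = 1 / fs)
    idx <- rr + 160 + seq_along(up) - 1
    pox[idx] <- 0.5 * (1 - cos(pi * up / 0.08))
  }
  got <- compute_invptt(r, pox, fs)
  expect_equal(got$invptt[1:2], c(5, 5), tolerance = 0.02)

  flat <- compute_invptt(r, rep(1, 4000), fs)
  expect_true(all(!flat$valid))
  expect_true(all(flat$reason == "no_pox_upstroke"))
  expect_error(compute_invptt(integer(0), pox, fs),
               class = "phonopress_insufficient_data_error")
})

test_that("invPTT recovers the simulator transit times within 3%", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  tb <- sim$truth
  fs <- rec$sampling_rate
  rp <- detect_r_peaks(rec$channels$ECG, fs)
  got <- compute_invptt(rp, rec$channels$POX, fs)
  idx <- match_beats((rp[-length(rp)] - 1) / fs, tb)
  rel <- abs(got$invptt * tb$ptt[idx] - 1)
  expect_true(all(rel[got$valid] < 0.03))
})

test_that("the assembled table has one full predictor row per clean beat", {
  sim <- sim_spont_clean()
  rec <- sim$records[[1]]
  sr <- segment_record(rec)
  ft <- assemble_feature_table(sr$segmentation, rec$channels$MIC,
                               rec$channels$POX, rec$sampling_rate)
  expect_lte(nrow(ft), sum(sr$segmentation$beats$valid))
  expect_equal(sum(!ft$valid), 0L)   # noise-free: nothing flagged
  expect_equal(sum(grepl("^sysB_dd", names(ft))), 13L)
  expect_equal(sum(grepl("^diaB_dd", names(ft))), 13L)
  # bit-identical determinism
  ft2 <- assemble_feature_table(sr$segmentation, rec$channels$MIC,
                                rec$channels$POX, rec$sampling_rate)
  expect_identical(ft, ft2)
})
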