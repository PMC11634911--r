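#' Spectrogram configuration
#'
#' Defaults: 25 ms Hann frames, 10 ms hop, FFT length the next power of two
#' at or above the frame length, 32 triangular mel bands spanning
#' 20--500 Hz on the scale `mel = 2595 * log10(1 + f/700)`. These keep at
#' least a dozen frames inside the shortest systole of the pacing protocol
#' (about 140 ms at 160 beats/min), enough context for the delta-delta
#' operator.
#'
#' @param frame frame length, seconds.
#' @param hop hop between frames, seconds.
#' @param n_mels number of mel bands.
#' @param fmin,fmax filterbank frequency range, Hz.
#' @param n_mfcc number of cepstral coefficients kept.
#' @param mfcc_offset first cepstral coefficient kept (0 keeps coefficients
#'   0..12; 1 keeps 1..13).
#' @return a `spectro_config` list.
#' @export
spectro_config <- function(frame = 0.025, hop = 0.010, n_mels = 32L,
                           fmin = 20, fmax = 500, n_mfcc = 13L,
                           mfcc_offset = 0L) {
  assert_that(frame > 0 && hop > 0 && fmax > fmin && fmin >= 0,
              "invalid spectrogram configuration")
  structure(list(frame = frame, hop = hop, n_mels = as.integer(n_mels),
                 fmin = fmin, fmax = fmax, n_mfcc = as.integer(n_mfcc),
                 mfcc_offset = as.integer(mfcc_offset)),
            class = "spectro_config")
}

#' @noRd
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @noRd
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank sampled at the FFT bin frequencies.
#' @noRd
mel_filterbank <- function(n_mels, nfft, fs, fmin, fmax) {
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
                         length.out = n_mels + 2L))
  bins <- (0:(nfft / 2)) * fs / nfft
  fb <- matrix(0, nrow = n_mels, ncol = length(bins))
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; mid <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bins - lo) / (mid - lo)
    down <- (hi - bins) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  list(weights = fb, centers = edges[2:(n_mels + 1L)])
}

#' Mel-band spectrogram of a phonocardiogram segment
#'
#' Short-time power spectrum on a mel-spaced frequency axis. A segment
#' shorter than one frame is analyzed as a single zero-padded frame.
#'
#' @param segment numeric vector.
#' @param sampling_rate Hz.
#' @param cfg a [spectro_config()].
#' @return a `mel_spectrogram` list: `energies` (frames x bands,
#'   nonnegative), `band_centers` (Hz), `frame_times` (s), `frame`, `hop`.
#' @export
mel_spectrogram <- function(segment, sampling_rate, cfg = spectro_config()) {
  fs <- sampling_rate
  assert_that(cfg$fmax <= fs / 2, "mel band range exceeds Nyquist")
  wlen <- round(cfg$frame * fs)
  hopn <- max(1L, round(cfg$hop * fs))
  L <- length(segment)
  if (L < wlen) {
    segment <- c(segment, rep(0, wlen - L))
    L <- wlen
  }
  n_frames <- floor((L - wlen) / hopn) + 1L
  nfft <- next_pow2(wlen)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(wlen - 1L)) / (wlen - 1L))  # Hann
  fb <- mel_filterbank(cfg$n_mels, nfft, fs, cfg$fmin, cfg$fmax)
  energies <- matrix(0, nrow = n_frames, ncol = cfg$n_mels)
  starts <- (seq_len(n_frames) - 1L) * hopn + 1L
  for (f in seq_len(n_frames)) {
    fr <- segment[starts[f]:(starts[f] + wlen - 1L)] * win
    spec <- stats::fft(c(fr, rep(0, nfft - wlen)))
    pow <- Mod(spec[1:(nfft / 2 + 1L)])^2
    energies[f, ] <- as.numeric(fb$weights %*% pow)
  }
  structure(
    list(energies = energies, band_centers = fb$centers,
         frame_times = (starts - 1L + wlen / 2) / fs,
         frame = cfg$frame, hop = cfg$hop),
    class = "mel_spectrogram"
  )
}

#' Spectral shape descriptors (set A)
#'
#' Frame-wise descriptors of the mel spectrum, averaged over frames
#' (frame pairs for flux). With band energies `s_k` at centers `f_k`:
#' centroid `mu = sum(f*s)/sum(s)`; spread `sigma`; skewness and kurtosis
#' the third and fourth standardized spectral moments; slope the
#' least-squares slope of energy against band center; flux the Euclidean
#' norm of the difference of unit-sum-normalized consecutive frames.
#' Frames with zero total energy or zero spread are skipped; if every frame
#' is degenerate the result carries `valid = FALSE` with reason
#' `"degenerate_spectrum"`.
#'
#' @param spec a `mel_spectrogram`.
#' @return list: `flux`, `kurtosis`, `skewness`, `slope`, `valid`,
#'   `reason`.
#' @export
spectral_features_set_a <- function(spec) {
  e <- spec$energies
  f <- spec$band_centers
  n <- nrow(e)
  kurt <- skew <- slope <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- e[i, ]
    tot <- sum(s)
    if (tot <= 0) next
    mu <- sum(f * s) / tot
    v <- sum((f - mu)^2 * s) / tot
    if (v <= 0) next
    sd3 <- v^1.5; sd4 <- v^2
    skew[i] <- sum((f - mu)^3 * s) / (sd3 * tot)
    kurt[i] <- sum((f - mu)^4 * s) / (sd4 * tot)
    fm <- mean(f); sm <- mean(s)
    slope[i] <- sum((f - fm) * (s - sm)) / sum((f - fm)^2)
  }
  ok <- !is.na(kurt)
  if (!any(ok)) {
    return(list(flux = NA_real_, kurtosis = NA_real_, skewness = NA_real_,
                slope = NA_real_, valid = FALSE,
                reason = "degenerate_spectrum"))
  }
  flux <- 0
  if (n >= 2L) {
    fluxes <- c()
    for (i in 2:n) {
      a <- e[i - 1L, ]; b <- e[i, ]
      if (sum(a) <= 0 || sum(b) <= 0) next
      fluxes <- c(fluxes, sqrt(sum((b / sum(b) - a / sum(a))^2)))
    }
    flux <- if (length(fluxes) > 0L) mean(fluxes) else 0
  }
  list(flux = flux, kurtosis = mean(kurt[ok]), skewness = mean(skew[ok]),
       slope = mean(slope[ok]), valid = TRUE, reason = NA_character_)
}

# Orthonormal type-II DCT matrix (k x N).
#' @noRd
dct_matrix <- function(k, N) {
  M <- matrix(0, k, N)
  for (r in seq_len(k)) {
    kk <- r - 1L
    M[r, ] <- cos(pi * kk * (seq_len(N) - 0.5) / N) * sqrt(2 / N)
    if (kk == 0L) M[r, ] <- M[r, ] / sqrt(2)
  }
  M
}

# Regression-style delta over frames (rows), window N = 2, edges replicated.
#' @noRd
delta_frames <- function(mat, N = 2L) {
  T <- nrow(mat)
  pad <- rbind(
    mat[rep(1L, N), , drop = FALSE], mat,
    mat[rep(T, N), , drop = FALSE]
  )
  denom <- 2 * sum((1:N)^2)
  out <- matrix(0, T, ncol(mat))
  for (t in seq_len(T)) {
    tc <- t + N
    acc <- 0
    for (n in 1:N) {
      acc <- acc + n * (pad[tc + n, ] - pad[tc - n, ])
    }
    out[t, ] <- acc / denom
  }
  out
}

#' Delta-delta mel-frequency cepstral coefficients (set B)
#'
#' Per frame, the cepstra are the orthonormal type-II DCT of
#' `log(energy + 1e-10)`, keeping 13 coefficients; the second temporal
#' derivative (delta of delta, regression window 2, edge frames
#' replicated) is averaged over frames.
#'
#' @param spec a `mel_spectrogram`.
#' @param cfg a [spectro_config()] (controls the coefficient offset).
#' @return numeric vector of exactly 13 values.
#' @export
mfcc_delta_delta <- function(spec, cfg = spectro_config()) {
  e <- spec$energies
  logE <- log(e + 1e-10)
  n_keep <- cfg$n_mfcc + cfg$mfcc_offset
  D <- dct_matrix(n_keep, ncol(e))
  cep <- logE %*% t(D)                      # frames x coefficients
  cep <- cep[, (cfg$mfcc_offset + 1L):n_keep, drop = FALSE]
  dd <- delta_frames(delta_frames(cep))
  colMeans(dd)
}

#' Inverse pulse transit time per beat
#'
#' For each beat the pulse transit time is the delay from the R-peak to the
#' maximum of the first derivative of the POX waveform (steepest systolic
#' upstroke of the peripheral pulse) within `(r, r + 0.6 * RR]`; invPTT is
#' its reciprocal. Beats with no positive upslope in the window are flagged
#' `"no_pox_upstroke"`.
#'
#' The waveform is smoothed (25 ms moving average) before differentiation:
#' the plethysmographic upstroke has a bandwidth of a few hertz, so the
#' smoothing suppresses broadband sensor noise without biasing the
#' upstroke's midpoint.
#'
#' @param r_peaks strictly increasing R-peak sample indices.
#' @param pox numeric POX vector.
#' @param sampling_rate Hz.
#' @param smooth_window smoothing window in seconds (default 0.025).
#' @return data frame: `beat`, `ptt` (s), `invptt` (1/s), `valid`,
#'   `reason`; one row per RR interval.
#' @export
compute_invptt <- function(r_peaks, pox, sampling_rate,
                           smooth_window = 0.025) {
  if (length(r_peaks) < 2L) {
    stop_phonopress("need at least 2 R-peaks for invPTT",
                    "phonopress_insufficient_data_error")
  }
  fs <- sampling_rate
  k <- max(1L, round(smooth_window * fs))
  pox <- moving_average(pox, k)
  n <- length(pox)
  d <- numeric(n)
  d[2:(n - 1L)] <- (pox[3:n] - pox[1:(n - 2L)]) * fs / 2
  nb <- length(r_peaks) - 1L
  ptt <- rep(NA_real_, nb)
  valid <- rep(TRUE, nb)
  reason <- rep(NA_character_, nb)
  for (i in seq_len(nb)) {
    r <- r_peaks[i]
    rr <- r_peaks[i + 1L] - r
    lo <- r + 1L
    hi <- min(r + round(0.6 * rr), length(pox))
    if (hi <= lo) { valid[i] <- FALSE; reason[i] <- "no_pox_upstroke"; next }
    w <- d[lo:hi]
    j <- which.max(w)
    if (w[j] <= 0) { valid[i] <- FALSE; reason[i] <- "no_pox_upstroke"; next }
    ptt[i] <- (lo - 1L + j - r) / fs
  }
  data.frame(beat = seq_len(nb), ptt = ptt, invptt = 1 / ptt,
             valid = valid, reason = reason, stringsAsFactors = FALSE)
}

#' Per-beat, per-phase predictor table
#'
#' For each valid beat of the segmentation, computes set A (spectral flux,
#' kurtosis, skewness, slope) and set B (13 delta-delta MFCCs) on the
#' systolic (`[onset, boundary)`) and diastolic (`[boundary, end)`) MIC
#' segments, and attaches the beat's invPTT. A beat-phase missing any
#' feature is flagged and excluded from regression.
#'
#' @param seg a `beat_segmentation`.
#' @param mic,pox numeric channel vectors.
#' @param sampling_rate Hz.
#' @param cfg a [spectro_config()].
#' @return a `beat_feature_table` data frame with one row per valid beat:
#'   `beat`, `invptt`, `sysA_flux`..`sysA_slope`, `sysB_dd00`..`sysB_dd12`,
#'   `diaA_*`, `diaB_*`, `valid`, `reason`.
#' @export
assemble_feature_table <- function(seg, mic, pox, sampling_rate,
                                   cfg = spectro_config()) {
  beats <- seg$beats[seg$beats$valid, , drop = FALSE]
  if (nrow(beats) == 0L) {
    warning("no valid beats; returning empty feature table")
    return(empty_feature_table(cfg))
  }
  iptt <- compute_invptt(seg$r_peaks, pox, sampling_rate)
  rows <- vector("list", nrow(beats))
  for (k in seq_len(nrow(beats))) {
    b <- beats[k, ]
    phases <- list(
      sys = mic[b$onset:(b$boundary - 1L)],
      dia = mic[b$boundary:(b$end - 1L)]
    )
    row <- list(beat = b$beat)
    valid <- TRUE; reason <- NA_character_
    for (ph in names(phases)) {
      spec <- mel_spectrogram(phases[[ph]], sampling_rate, cfg)
      a <- spectral_features_set_a(spec)
      if (!isTRUE(a$valid)) { valid <- FALSE; reason <- a$reason }
      row[[paste0(ph, "A_flux")]] <- a$flux
      row[[paste0(ph, "A_kurtosis")]] <- a$kurtosis
      row[[paste0(ph, "A_skewness")]] <- a$skewness
      row[[paste0(ph, "A_slope")]] <- a$slope
      dd <- mfcc_delta_delta(spec, cfg)
      for (j in seq_along(dd)) {
        row[[sprintf("%sB_dd%02d", ph, j - 1L)]] <- dd[j]
      }
    }
    ib <- iptt[iptt$beat == b$beat, ]
    if (nrow(ib) == 1L && isTRUE(ib$valid)) {
      row$invptt <- ib$invptt
    } else {
      row$invptt <- NA_real_
      valid <- FALSE
      reason <- if (nrow(ib) == 1L) ib$reason else "no_pox_upstroke"
    }
    row$valid <- valid
    row$reason <- reason
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  front <- c("beat", "invptt")
  out <- out[, c(front, setdiff(names(out), c(front, "valid", "reason")),
                 "valid", "reason")]
  structure(out, class = c("beat_feature_table", "data.frame"))
}

#' @noRd
feature_column_names <- function(cfg = spectro_config()) {
  dd <- sprintf("dd%02d", seq_len(cfg$n_mfcc) - 1L)
  c("beat", "invptt",
    paste0("sysA_", c("flux", "kurtosis", "skewness", "slope")),
    paste0("sysB_", dd),
    paste0("diaA_", c("flux", "kurtosis", "skewness", "slope")),
    paste0("diaB_", dd),
    "valid", "reason")
}

#' @noRd
empty_feature_table <- function(cfg = spectro_config()) {
  nms <- feature_column_names(cfg)
  out <- as.data.frame(stats::setNames(
    lapply(nms, function(nm) {
      switch(nm, beat = integer(0), valid = logical(0),
             reason = character(0), numeric(0))
    }), nms), stringsAsFactors = FALSE)
  structure(out, class = c("beat_feature_table", "data.frame"))
}
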