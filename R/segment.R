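#' Detect R-peaks in an ECG trace
#'
#' Energy-based QRS detector: band-pass 5--30 Hz, differentiate, square,
#' moving-window integrate (120 ms), adaptive threshold at 0.4 times a
#' rolling 95th percentile of the integrated energy, 240 ms refractory
#' period. Each candidate is refined to the absolute maximum of the
#' band-passed ECG within +/- 80 ms, so the reported index sits on the R
#' wave itself. The threshold is relative, hence the output is invariant to
#' positive rescaling of the ECG.
#'
#' @param ecg numeric vector (V).
#' @param sampling_rate Hz.
#' @return strictly increasing integer sample indices (possibly empty, with
#'   a warning, when no QRS energy is found).
#' @export
detect_r_peaks <- function(ecg, sampling_rate) {
  fs <- sampling_rate
  assert_that(length(ecg) >= 2 * fs, "need at least 2 s of ECG")
  if (stats::sd(ecg) == 0) {
    warning("ECG is constant; no R-peaks detected")
    return(integer(0))
  }
  nyq <- fs / 2
  bf <- signal::butter(2, c(5, min(30, 0.9 * nyq)) / nyq, type = "pass")
  x <- signal::filtfilt(bf, ecg - mean(ecg))
  d <- c(0, diff(x)) * fs
  energy <- moving_average(d^2, max(3L, round(0.12 * fs)))
  # rolling 95th percentile over ~10 s blocks, interpolated
  block <- max(2L, round(10 * fs))
  starts <- seq(1L, length(energy), by = block)
  q <- vapply(starts, function(s) {
    stats::quantile(energy[s:min(s + block - 1L, length(energy))], 0.95,
                    names = FALSE)
  }, numeric(1))
  centers <- pmin(starts + block %/% 2L, length(energy))
  thr_level <- if (length(q) > 1L) {
    stats::approx(centers, q, xout = seq_along(energy), rule = 2)$y
  } else rep(q, length(energy))
  thr <- 0.4 * thr_level
  above <- energy > thr & thr > 0
  if (!any(above)) {
    warning("no QRS energy above threshold; no R-peaks detected")
    return(integer(0))
  }
  # contiguous supra-threshold regions -> one candidate each
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  cand <- integer(0)
  half <- round(0.08 * fs)
  for (k in which(r$values)) {
    a <- begins[k]; b <- ends[k]
    lo <- max(1L, a - half); hi <- min(length(x), b + half)
    cand <- c(cand, lo - 1L + which.max(abs(x[lo:hi])))
  }
  cand <- sort(unique(cand))
  # refractory: 240 ms, keep the stronger peak
  refr <- round(0.24 * fs)
  keep <- integer(0)
  for (p in cand) {
    if (length(keep) == 0L || p - keep[length(keep)] > refr) {
      keep <- c(keep, p)
    } else if (abs(x[p]) > abs(x[keep[length(keep)]])) {
      keep[length(keep)] <- p
    }
  }
  keep
}

#' Heart rate from R-peaks
#'
#' `HR = 60 / median(RR)` over the detected R-peak series.
#'
#' @param r_peaks strictly increasing sample indices (>= 3).
#' @param sampling_rate Hz.
#' @return heart rate in beats/min.
#' @export
estimate_hr <- function(r_peaks, sampling_rate) {
  if (length(r_peaks) < 3L) {
    stop_phonopress("need at least 3 R-peaks to estimate heart rate",
                    "phonopress_insufficient_data_error")
  }
  60 / stats::median(diff(r_peaks) / sampling_rate)
}

#' Select a hemodynamically stable segment
#'
#' Finds the longest contiguous window of at least `min_duration` seconds in
#' which every beat's stability proxy lies within `+/- tolerance` of the
#' window median. The proxy is the per-beat maximum of LVP when present,
#' otherwise the per-beat POX pulse amplitude (max - min). If the whole
#' record qualifies it is returned in full.
#'
#' @param record a [signal_record()].
#' @param r_peaks R-peak sample indices.
#' @param min_duration minimum window length in seconds (default 180).
#' @param tolerance relative deviation allowed around the window median
#'   (default 0.10).
#' @return list with `start` and `end` (sample indices), `n_beats`, and the
#'   `beats` (indices into `r_peaks`) retained.
#' @export
select_stable_segment <- function(record, r_peaks, min_duration = 180,
                                  tolerance = 0.10) {
  fs <- record$sampling_rate
  nb <- length(r_peaks) - 1L
  assert_that(nb >= 1L, "need at least 2 R-peaks",
              "phonopress_insufficient_data_error")
  proxy <- numeric(nb)
  use_lvp <- "LVP" %in% names(record$channels)
  src <- if (use_lvp) record$channels$LVP else record$channels$POX
  for (i in seq_len(nb)) {
    seg <- src[r_peaks[i]:(r_peaks[i + 1L] - 1L)]
    proxy[i] <- if (use_lvp) max(seg) else max(seg) - min(seg)
  }
  beat_dur <- diff(r_peaks) / fs
  ok_window <- function(a, b) {
    w <- proxy[a:b]
    m <- stats::median(w)
    all(abs(w - m) <= tolerance * abs(m))
  }
  win_dur <- function(a, b) (r_peaks[b + 1L] - r_peaks[a]) / fs
  # whole record first (the common case), then longest-to-shortest scan
  best <- NULL
  if (ok_window(1L, nb)) {
    best <- c(1L, nb)
  } else {
    for (len in nb:1) {
      found <- FALSE
      for (a in 1:(nb - len + 1L)) {
        b <- a + len - 1L
        if (win_dur(a, b) < min_duration) next
        if (ok_window(a, b)) { best <- c(a, b); found <- TRUE; break }
      }
      if (found) break
      if (max(vapply(1:(nb - len + 1L),
                     function(a) win_dur(a, a + len - 1L), numeric(1))) <
          min_duration) break
    }
  }
  if (is.null(best) || win_dur(best[1L], best[2L]) < min_duration) {
    achievable <- if (is.null(best)) 0 else win_dur(best[1L], best[2L])
    longest <- max(vapply(seq_len(nb), function(a) {
      b <- a
      while (b < nb && ok_window(a, b + 1L)) b <- b + 1L
      win_dur(a, b)
    }, numeric(1)), achievable)
    stop_phonopress(
      sprintf(paste0("no stable segment of >= %.0f s found ",
                     "(best achievable: %.1f s)"), min_duration, longest),
      "phonopress_no_stable_segment_error"
    )
  }
  list(start = r_peaks[best[1L]], end = r_peaks[best[2L] + 1L] - 1L,
       n_beats = best[2L] - best[1L] + 1L, beats = best[1L]:best[2L])
}

#' Upper and lower envelopes of the phonocardiogram
#'
#' `sliding_extrema` (default): moving maximum/minimum over `window`
#' seconds followed by a moving-average smoothing of the same width;
#' guarantees `upper >= lower` pointwise. `spline_peaks`: cubic-spline
#' interpolation through local maxima/minima separated by at least
#' `window` seconds.
#'
#' @param mic numeric vector (mmHg).
#' @param sampling_rate Hz.
#' @param method `"sliding_extrema"` or `"spline_peaks"`.
#' @param window envelope window in seconds (default 0.05).
#' @return list with numeric vectors `upper` and `lower`, each the length
#'   of `mic`.
#' @export
compute_envelopes <- function(mic, sampling_rate,
                              method = c("sliding_extrema", "spline_peaks"),
                              window = 0.05) {
  method <- match.arg(method)
  k <- round(window * sampling_rate)
  assert_that(k > 2, "envelope window must span more than 2 samples")
  if (method == "sliding_extrema") {
    upper <- moving_average(rolling_extreme(mic, k, "max"), k)
    lower <- moving_average(rolling_extreme(mic, k, "min"), k)
  } else {
    upper <- spline_envelope(mic, k, "max")
    lower <- spline_envelope(mic, k, "min")
  }
  list(upper = upper, lower = lower)
}

#' @noRd
spline_envelope <- function(x, k, which) {
  n <- length(x)
  sgn <- if (which == "max") 1 else -1
  y <- sgn * x
  ext <- local_minima(-y)          # local maxima of y
  if (length(ext) >= 2L) {
    # enforce minimum separation k, keeping the larger peak
    keep <- ext[1L]
    for (p in ext[-1L]) {
      last <- keep[length(keep)]
      if (p - last >= k) keep <- c(keep, p)
      else if (y[p] > y[last]) keep[length(keep)] <- p
    }
    ext <- keep
  }
  if (length(ext) < 2L) return(rep(if (which == "max") max(x) else min(x), n))
  knots_x <- c(1L, ext, n)
  knots_y <- y[knots_x]
  env <- stats::spline(knots_x, knots_y, xout = seq_len(n))$y
  sgn * env
}

#' Microphone envelope difference (MED) signal
#'
#' `med_raw = upper - lower`; `med_filtered` is a zero-phase band-pass of
#' `med_raw` whose passband is `[0.7, 1.3]` times the heart-rate fundamental
#' (`hr/60` Hz), realized as a 4th-order Butterworth applied
#' forward-backward so minima timing is preserved.
#'
#' @param upper,lower envelope vectors from [compute_envelopes()].
#' @param hr heart rate in beats/min (from [estimate_hr()]).
#' @param sampling_rate Hz.
#' @param method envelope method used (stored for provenance).
#' @return a `med_signal` list: `upper`, `lower`, `med_raw`,
#'   `med_filtered`, `method`, `passband`.
#' @export
compute_med <- function(upper, lower, hr, sampling_rate,
                        method = "sliding_extrema") {
  f0 <- hr / 60
  band <- c(0.7, 1.3) * f0
  nyq <- sampling_rate / 2
  assert_that(band[2L] < nyq, "MED passband upper edge reaches Nyquist")
  med_raw <- upper - lower
  bf <- signal::butter(2, band / nyq, type = "pass")
  med_filtered <- signal::filtfilt(bf, med_raw - mean(med_raw))
  structure(
    list(upper = upper, lower = lower, med_raw = med_raw,
         med_filtered = med_filtered, method = method, passband = band),
    class = "med_signal"
  )
}

#' Segment beats into systole and diastole from MED minima
#'
#' For each RR interval the systole/diastole boundary is the deepest local
#' minimum of `med_filtered` within `[0.2, 0.6] * RR` after the R-peak
#' (ties resolve to the earliest). Beats with no local minimum in the
#' window are flagged invalid with reason `"no_med_minimum"`; beats shorter
#' than 250 ms are flagged `"rr_too_short"`.
#'
#' @param med a `med_signal` from [compute_med()].
#' @param r_peaks strictly increasing R-peak sample indices (>= 2).
#' @param sampling_rate Hz.
#' @return a `beat_segmentation` list: `r_peaks`, `hr`, and data frame
#'   `beats` with columns `beat`, `onset`, `boundary`, `end` (sample
#'   indices), `valid`, `reason`.
#' @export
segment_beats <- function(med, r_peaks, sampling_rate) {
  if (length(r_peaks) < 2L) {
    stop_phonopress("need at least 2 R-peaks to segment beats",
                    "phonopress_insufficient_data_error")
  }
  x <- med$med_filtered
  nb <- length(r_peaks) - 1L
  onset <- r_peaks[-length(r_peaks)]
  endp <- r_peaks[-1L]
  boundary <- rep(NA_integer_, nb)
  valid <- rep(TRUE, nb)
  reason <- rep(NA_character_, nb)
  for (i in seq_len(nb)) {
    rr <- endp[i] - onset[i]
    if (rr / sampling_rate < 0.25) {
      valid[i] <- FALSE; reason[i] <- "rr_too_short"; next
    }
    lo <- onset[i] + max(1L, round(0.2 * rr))
    hi <- onset[i] + round(0.6 * rr)
    hi <- min(hi, length(x))
    if (hi - lo < 2L) {
      valid[i] <- FALSE; reason[i] <- "no_med_minimum"; next
    }
    w <- x[lo:hi]
    mins <- local_minima(w)
    if (length(mins) == 0L) {
      valid[i] <- FALSE; reason[i] <- "no_med_minimum"; next
    }
    boundary[i] <- lo - 1L + mins[which.min(w[mins])]
  }
  hr <- estimate_hr(r_peaks, sampling_rate)
  structure(
    list(
      r_peaks = r_peaks,
      hr = hr,
      sampling_rate = sampling_rate,
      beats = data.frame(
        beat = seq_len(nb), onset = onset, boundary = boundary, end = endp,
        valid = valid, reason = reason, stringsAsFactors = FALSE
      )
    ),
    class = "beat_segmentation"
  )
}

#' @export
print.beat_segmentation <- function(x, ...) {
  cat(sprintf(
    "<beat_segmentation> %d beats (%d valid), HR %.1f bpm\n",
    nrow(x$beats), sum(x$beats$valid), x$hr
  ))
  invisible(x)
}

#' Full segmentation of one recording step
#'
#' Convenience wrapper running R-peak detection, HR estimation, envelope and
#' MED computation, and beat segmentation on one [signal_record()].
#'
#' @param record a [signal_record()].
#' @param envelope_method passed to [compute_envelopes()].
#' @param envelope_window seconds (default 0.05).
#' @return list with `segmentation` (a `beat_segmentation`) and `med`
#'   (a `med_signal`).
#' @export
segment_record <- function(record, envelope_method = "sliding_extrema",
                           envelope_window = 0.05) {
  fs <- record$sampling_rate
  rp <- detect_r_peaks(record$channels$ECG, fs)
  assert_that(length(rp) >= 3L, "too few R-peaks detected",
              "phonopress_insufficient_data_error")
  hr <- estimate_hr(rp, fs)
  env <- compute_envelopes(record$channels$MIC, fs,
                           method = envelope_method,
                           window = envelope_window)
  med <- compute_med(env$upper, env$lower, hr, fs, method = envelope_method)
  seg <- segment_beats(med, rp, fs)
  list(segmentation = seg, med = med)
}
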