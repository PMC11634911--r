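#' Pacing protocol specification
#'
#' The standard hemodynamic stress protocol records one step at the
#' spontaneous heart rate followed by incremental right-ventricular pacing
#' in 20 beats/min increments up to 160 beats/min: five steps in total.
#'
#' @param spontaneous_hr spontaneous heart rate, beats/min (30--250).
#' @param step_duration duration of every step in seconds (>= 10; default
#'   180 s, i.e. at least 3 minutes of stable recording per step).
#' @return a `protocol_spec`: data frame with columns `label`,
#'   `pacing_rate` (beats/min) and `duration` (s).
#' @export
default_protocol <- function(spontaneous_hr = 78, step_duration = 180) {
  protocol_spec(
    labels = c("spontaneous", "100bpm", "120bpm", "140bpm", "160bpm"),
    pacing_rates = c(spontaneous_hr, 100, 120, 140, 160),
    durations = rep(step_duration, 5L)
  )
}

#' @rdname default_protocol
#' @param labels step labels.
#' @param pacing_rates imposed heart rate per step, beats/min.
#' @param durations step durations, seconds.
#' @export
protocol_spec <- function(labels, pacing_rates, durations) {
  assert_that(length(labels) == length(pacing_rates) &&
                length(labels) == length(durations),
              "protocol fields must have equal length")
  assert_that(all(pacing_rates >= 30 & pacing_rates <= 250),
              "pacing rates must lie in [30, 250] beats/min")
  assert_that(all(durations >= 10), "step durations must be >= 10 s")
  structure(
    data.frame(label = as.character(labels),
               pacing_rate = as.numeric(pacing_rates),
               duration = as.numeric(durations),
               stringsAsFactors = FALSE),
    class = c("protocol_spec", "data.frame")
  )
}

#' Hemodynamic preset
#'
#' Baseline per-beat hemodynamics around which the simulator perturbs.
#' The two named presets reproduce the baseline characteristics of a
#' healthy and a tachypacing-induced HFrEF Goettingen minipig:
#' heart rate 78 beats/min in both; EDP 5.70 vs 15.45 mmHg; ESP 64.81 vs
#' 77.65 mmHg; dPdt_max 1168.75 vs 581.55 mmHg/s.
#'
#' @param label `"healthy"`, `"hfref"` or `"custom"`.
#' @param mean_hr,mean_edp,mean_esp,mean_dpdtmax overrides for a custom
#'   preset (beats/min, mmHg, mmHg, mmHg/s).
#' @return a `hemodynamic_preset` list.
#' @export
hemodynamic_preset <- function(label = c("hfref", "healthy", "custom"),
                               mean_hr = NULL, mean_edp = NULL,
                               mean_esp = NULL, mean_dpdtmax = NULL) {
  label <- match.arg(label)
  base <- switch(label,
    healthy = list(mean_hr = 78, mean_edp = 5.70, mean_esp = 64.81,
                   mean_dpdtmax = 1168.75),
    hfref   = list(mean_hr = 78, mean_edp = 15.45, mean_esp = 77.65,
                   mean_dpdtmax = 581.55),
    custom  = list(mean_hr = 78, mean_edp = 8, mean_esp = 70,
                   mean_dpdtmax = 900)
  )
  for (nm in c("mean_hr", "mean_edp", "mean_esp", "mean_dpdtmax")) {
    v <- get(nm)
    if (!is.null(v)) base[[nm]] <- as.numeric(v)
  }
  assert_that(base$mean_esp > base$mean_edp && base$mean_edp > 0,
              "preset requires mean_esp > mean_edp > 0")
  assert_that(base$mean_dpdtmax > 0, "preset requires mean_dpdtmax > 0")
  structure(c(base, list(label = label)), class = "hemodynamic_preset")
}

#' Beat-to-beat coupling configuration
#'
#' Controls the latent beat-to-beat variability and how the rendered
#' non-invasive channels encode the pressure indices:
#' \itemize{
#' \item the three indices follow stationary AR(1) chains around the preset
#'   means with relative standard deviation `sigma` and lag-1 coefficient
#'   `rho`;
#' \item pulse transit time is negatively coupled to end-systolic pressure:
#'   `ptt = ptt_intercept + ptt_slope * (esp - mean_esp)`, floored at 50 ms
#'   (`ptt_slope <= 0`, reflecting the established negative PTT/systolic
#'   pressure correlation);
#' \item S1 burst gain is affine in dPdt_max and its carrier frequency in
#'   EDP; S2 burst gain and carrier frequency are affine in ESP, so the
#'   systolic and diastolic heart-sound spectra carry the indices that the
#'   downstream regression is asked to recover;
#' \item a diastolic filling sound (gallop) is rendered per beat, with
#'   amplitude and timing solved so that the heart-rate-bandpassed envelope
#'   difference (MED) attains its per-cycle minimum at the true
#'   systole/diastole boundary (see the methods vignette).
#' }
#'
#' @param sigma relative AR(1) standard deviation of the indices (fraction
#'   of the preset mean; default 0.05).
#' @param rho AR(1) lag-1 coefficient, in `[0, 1)`.
#' @param rr_jitter relative standard deviation of the RR interval
#'   (default 0.02).
#' @param ptt_intercept baseline pulse transit time, seconds.
#' @param ptt_slope PTT change per mmHg of ESP deviation (s/mmHg, <= 0).
#' @param s1_gain,s2_gain baseline burst peak amplitudes, mmHg.
#' @param gain_dpdt_coeff relative S1 gain change per relative dPdt_max
#'   deviation.
#' @param freq_edp_coeff relative S1 carrier-frequency change per relative
#'   EDP deviation.
#' @param gain_esp_coeff,freq_esp_coeff relative S2 gain/frequency change
#'   per relative ESP deviation.
#' @param diastolic_sound render the diastolic filling sound (default
#'   `TRUE`); with `FALSE` the phonocardiogram is strictly silent between
#'   the S2 tail and the next S1.
#' @param diastolic_gain cap on the gallop burst amplitude, as a fraction
#'   of the summed S1/S2 gains.
#' @return a `coupling_config` list.
#' @export
coupling_config <- function(sigma = 0.05, rho = 0.5, rr_jitter = 0.02,
                            ptt_intercept = 0.15, ptt_slope = -0.0015,
                            s1_gain = 0.06, s2_gain = 0.045,
                            gain_dpdt_coeff = 2.0, freq_edp_coeff = 3.0,
                            gain_esp_coeff = 1.5, freq_esp_coeff = 1.5,
                            diastolic_sound = TRUE, diastolic_gain = 1.5,
                            burst_duration = 0.12) {
  assert_that(rho >= 0 && rho < 1, "AR(1) coefficient rho must be in [0, 1)")
  assert_that(ptt_slope <= 0, "ptt_slope must be <= 0")
  assert_that(sigma >= 0 && rr_jitter >= 0, "noise scales must be >= 0")
  structure(as.list(environment()), class = "coupling_config")
}

#' Additive channel noise configuration
#'
#' White Gaussian noise is added per channel at a configured signal-to-noise
#' ratio (dB, relative to the clean channel's AC power). `Inf` disables
#' noise. The scalar form applies `snr_db` to the three non-invasive
#' channels (ECG, MIC, POX); the invasive catheter LVP keeps its own,
#' much higher, default SNR (`lvp_snr_db`) because it serves as the
#' measurement reference. A named vector sets channels individually.
#'
#' @param snr_db scalar SNR for the non-invasive channels, or a named
#'   vector with any of `ECG`, `LVP`, `MIC`, `POX`.
#' @param lvp_snr_db SNR of the LVP channel when `snr_db` is a scalar
#'   (default 60 dB).
#' @return a `noise_config` list.
#' @export
noise_config <- function(snr_db = 20, lvp_snr_db = 60) {
  base <- c(ECG = NA_real_, LVP = NA_real_, MIC = NA_real_, POX = NA_real_)
  if (is.null(names(snr_db))) {
    base[] <- snr_db[1L]
    base["LVP"] <- if (is.finite(snr_db[1L])) lvp_snr_db else Inf
  } else {
    base[] <- Inf
    base[names(snr_db)] <- snr_db
  }
  structure(list(snr_db = base), class = "noise_config")
}

# Stationary AR(1) chain with mean 0, sd `sigma`, lag-1 coefficient `rho`.
#' @noRd
ar1_chain <- function(n, sigma, rho) {
  if (sigma == 0 || n == 0L) return(rep(0, n))
  z <- stats::rnorm(n)
  e <- numeric(n)
  e[1L] <- sigma * z[1L]
  if (n > 1L) {
    innov <- sigma * sqrt(1 - rho^2)
    for (i in 2:n) e[i] <- rho * e[i - 1L] + innov * z[i]
  }
  e
}

# Duration of systole for a beat of length rr seconds (Bazett-like scaling:
# the systolic fraction grows as diastole shortens under pacing).
#' @noRd
systole_duration <- function(rr) 0.32 * sqrt(rr)

#' Simulate per-beat hemodynamic ground truth
#'
#' Generates, for every step of the protocol, beat times with multiplicative
#' RR jitter and per-beat EDP, ESP and dPdt_max as stationary AR(1)
#' perturbations around the preset means, plus a pulse transit time
#' negatively coupled to ESP. Identical seeds give identical output.
#'
#' Beat times are expressed relative to the start of each step.
#'
#' @param protocol a [protocol_spec()].
#' @param preset a [hemodynamic_preset()].
#' @param coupling a [coupling_config()].
#' @param seed integer RNG seed (mandatory).
#' @return a `ground_truth` data frame with columns `step_label`, `beat`,
#'   `r_time`, `end_systole_time`, `rr`, `edp`, `esp`, `dpdtmax`, `ptt`
#'   (seconds / mmHg / mmHg/s); the protocol, preset and coupling travel as
#'   attributes.
#' @export
simulate_hemodynamics <- function(protocol, preset = hemodynamic_preset(),
                                  coupling = coupling_config(), seed) {
  assert_that(!missing(seed) && is_scalar_number(seed),
              "an integer seed is required")
  assert_that(inherits(protocol, "protocol_spec"), "not a protocol_spec")
  out <- with_seed(seed, {
    rows <- list()
    for (s in seq_len(nrow(protocol))) {
      hr <- protocol$pacing_rate[s]
      dur <- protocol$duration[s]
      rr_mean <- 60 / hr
      n_max <- ceiling(dur / rr_mean) + 10L
      jit <- pmax(pmin(stats::rnorm(n_max), 3), -3)
      rr <- rr_mean * (1 + coupling$rr_jitter * jit)
      r_time <- 0.3 + cumsum(c(0, rr))[seq_len(n_max)]
      keep <- (r_time + rr + 0.3) <= dur
      n <- sum(keep)
      assert_that(n >= 3L, "step too short to contain beats")
      rr <- rr[seq_len(n)]
      r_time <- r_time[seq_len(n)]
      edp <- preset$mean_edp * (1 + ar1_chain(n, coupling$sigma, coupling$rho))
      esp <- preset$mean_esp * (1 + ar1_chain(n, coupling$sigma, coupling$rho))
      dpdtmax <- preset$mean_dpdtmax *
        (1 + ar1_chain(n, coupling$sigma, coupling$rho))
      edp <- pmax(edp, 0.5)
      esp <- pmax(esp, edp * 1.5)
      ptt <- pmax(coupling$ptt_intercept +
                    coupling$ptt_slope * (esp - preset$mean_esp), 0.05)
      rows[[s]] <- data.frame(
        step_label = protocol$label[s],
        beat = seq_len(n),
        r_time = r_time,
        end_systole_time = r_time + systole_duration(rr),
        rr = rr,
        edp = edp, esp = esp, dpdtmax = dpdtmax, ptt = ptt,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
  structure(out,
            class = c("ground_truth", "data.frame"),
            protocol = protocol, preset = preset, coupling = coupling,
            seed = as.integer(seed))
}

# Add a waveform `w` starting at sample `i0` into `x` (clipped to bounds).
#' @noRd
add_into <- function(x, i0, w) {
  n <- length(x)
  idx <- i0 + seq_along(w) - 1L
  ok <- idx >= 1L & idx <= n
  x[idx[ok]] <- x[idx[ok]] + w[ok]
  x
}

#' @noRd
gaussian_bump <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

# Damped-oscillation heart-sound burst: raised-cosine envelope times a
# sinusoidal carrier, `dur` seconds long.
#' @noRd
sound_burst <- function(fs, dur, freq, gain, phase = 0) {
  v <- seq(0, dur, by = 1 / fs)
  env <- 0.5 * (1 - cos(2 * pi * v / dur))
  gain * env * sin(2 * pi * freq * v + phase)
}

#' Render the four channels from per-beat ground truth
#'
#' Produces one [signal_record()] per protocol step:
#' \itemize{
#' \item `ECG`: Gaussian QRS bump at every R time plus a T bump just before
#'   end-systole;
#' \item `LVP`: a piecewise raised-cosine/exponential beat that equals
#'   `edp_i` at `r_time_i`, attains maximum upstroke slope `dpdtmax_i`, and
#'   passes through `esp_i` at `end_systole_time_i`;
#' \item `MIC`: S1 burst at systole onset and S2 burst at end-systole whose
#'   gain and carrier frequency are affine in the pressure indices
#'   (coefficients from the coupling config), plus an optional diastolic
#'   filling sound;
#' \item `POX`: a pulse whose maximum-upslope instant lags `r_time_i` by
#'   exactly `ptt_i`.
#' }
#' White Gaussian noise is added per channel at the configured SNR.
#'
#' @param truth a `ground_truth` from [simulate_hemodynamics()].
#' @param sampling_rate sampling rate in Hz (>= 250; default 1000).
#' @param noise a [noise_config()] (`noise_config(Inf)` disables noise).
#' @param seed integer seed for the noise generator.
#' @return named list of [signal_record()], one per step.
#' @export
render_signals <- function(truth, sampling_rate = 1000,
                           noise = noise_config(), seed = 1L) {
  assert_that(inherits(truth, "ground_truth") && nrow(truth) > 0L,
              "truth must be a non-empty ground_truth")
  assert_that(sampling_rate >= 250, "sampling_rate must be >= 250 Hz")
  protocol <- attr(truth, "protocol")
  preset <- attr(truth, "preset")
  coupling <- attr(truth, "coupling")
  fs <- sampling_rate
  records <- list()
  for (s in seq_len(nrow(protocol))) {
    step <- protocol$label[s]
    tb <- truth[truth$step_label == step, , drop = FALSE]
    if (nrow(tb) == 0L) next
    n <- round(protocol$duration[s] * fs)
    tt <- (seq_len(n) - 1L) / fs
    ecg <- numeric(n)
    lvp <- rep(tb$edp[1L], n)
    mic <- numeric(n)
    pox <- numeric(n)
    nb <- nrow(tb)
    r_next <- c(tb$r_time[-1L], tb$r_time[nb] + tb$rr[nb])
    for (i in seq_len(nb)) {
      r <- tb$r_time[i]; ts <- tb$end_systole_time[i]; rn <- r_next[i]
      edp <- tb$edp[i]; esp <- tb$esp[i]; dpdt <- tb$dpdtmax[i]
      edp_next <- if (i < nb) tb$edp[i + 1L] else edp
      ## --- ECG ---------------------------------------------------------
      i_lo <- max(1L, floor((r - 0.12) * fs)); i_hi <- min(n, ceiling((rn) * fs))
      seg_t <- tt[i_lo:i_hi]
      ecg[i_lo:i_hi] <- ecg[i_lo:i_hi] +
        gaussian_bump(seg_t, r, 0.008, 1e-3) +           # QRS
        gaussian_bump(seg_t, ts - 0.04, 0.02, 2.5e-4) +  # T wave
        gaussian_bump(seg_t, r - 0.16, 0.02, 1e-4)       # P wave
      ## --- LVP ---------------------------------------------------------
      lvp <- render_lvp_beat(lvp, fs, r, ts, rn, edp, esp, dpdt, edp_next)
      ## --- MIC ---------------------------------------------------------
      rel_dpdt <- dpdt / preset$mean_dpdtmax - 1
      rel_edp <- edp / preset$mean_edp - 1
      rel_esp <- esp / preset$mean_esp - 1
      hf_boost <- if (identical(preset$label, "hfref")) 1.5 else 1.0
      g1 <- coupling$s1_gain * hf_boost *
        (1 + coupling$gain_dpdt_coeff * rel_dpdt)
      f1 <- 40 * (1 + coupling$freq_edp_coeff * rel_edp)
      g2 <- coupling$s2_gain * hf_boost *
        (1 + coupling$gain_esp_coeff * rel_esp)
      f2 <- 65 * (1 + coupling$freq_esp_coeff * rel_esp)
      dur_b <- coupling$burst_duration
      s1_on <- r + 0.01
      mic <- add_into(mic, round(s1_on * fs) + 1L,
                      sound_burst(fs, dur_b, f1, g1))
      mic <- add_into(mic, round(ts * fs) + 1L,
                      sound_burst(fs, dur_b, f2, g2))
      if (isTRUE(coupling$diastolic_sound)) {
        rr <- rn - r
        # the gallop may sit anywhere from the S2 tail up against the next
        # S1 (a pre-systolic gallop), hence the wide diastolic arc
        sol <- solve_diastolic_burst(
          g1 = g1, c1 = (s1_on - r + dur_b / 2) / rr,
          g2 = g2, c2 = (ts - r + dur_b / 2) / rr,
          frac_ts = (ts - r) / rr,
          lo = (ts - r + dur_b) / rr + 0.02, hi = 0.99,
          g_cap = coupling$diastolic_gain * (g1 + g2)
        )
        mic <- add_into(mic,
                        round((r + sol$center * rr - dur_b / 2) * fs) + 1L,
                        sound_burst(fs, dur_b, 45, sol$gain))
      }
      ## --- POX ---------------------------------------------------------
      a_pulse <- 1 + 0.5 * ((esp - edp) / (preset$mean_esp - preset$mean_edp) - 1)
      tau_r <- 0.08
      v0 <- r + tb$ptt[i] - tau_r / 2
      # one self-contained pulse: raised-cosine upstroke (max slope exactly
      # at r + ptt), raised-cosine decay back to baseline just before the
      # next beat's upstroke begins
      dec_end <- rn + tb$ptt[min(i + 1L, nb)] - tau_r / 2
      tau_d <- max(dec_end - (v0 + tau_r) - 1 / fs, 0.05)
      i0 <- floor(v0 * fs) + 1L
      i1 <- ceiling((v0 + tau_r + tau_d) * fs) + 1L
      v <- ((i0:i1) - 1L) / fs - v0   # evaluated on the exact sample grid
      w <- ifelse(v < 0, 0,
             ifelse(v <= tau_r,
                    0.5 * (1 - cos(pi * v / tau_r)),
                    0.5 * (1 + cos(pi * pmin((v - tau_r) / tau_d, 1)))))
      pox <- add_into(pox, i0, a_pulse * w)
    }
    # POX rides on a plethysmographic baseline
    pox <- pox + 40
    chans <- list(ECG = ecg, LVP = lvp, MIC = mic, POX = pox)
    snr <- noise$snr_db
    chans <- with_seed(seed + s, {
      for (nm in names(chans)) {
        sdb <- snr[[nm]]
        if (is.finite(sdb)) {
          ac_sd <- stats::sd(chans[[nm]])
          if (ac_sd > 0) {
            chans[[nm]] <- chans[[nm]] +
              stats::rnorm(n, sd = ac_sd / 10^(sdb / 20))
          }
        }
      }
      chans
    })
    records[[step]] <- signal_record(
      channels = chans, sampling_rate = fs, step_label = step,
      subject_label = preset$label, start_time = 0
    )
  }
  records
}

# One LVP beat: raised-cosine upstroke hitting max slope `dpdt` exactly,
# raised-cosine ejection decay through `esp` at `ts`, a short isovolumic
# shoulder, then an exponential relaxation corrected to end at the next
# beat's EDP.
#' @noRd
render_lvp_beat <- function(lvp, fs, r, ts, rn, edp, esp, dpdt, edp_next) {
  peak <- esp + 0.05 * (esp - edp)
  tau_up <- pi * (peak - edp) / (2 * dpdt)
  sys_dur <- ts - r
  if (tau_up > 0.95 * sys_dur) {
    tau_up <- 0.95 * sys_dur
    peak <- edp + 2 * dpdt * tau_up / pi
  }
  i_r <- round(r * fs) + 1L
  i_end <- round(rn * fs)        # last sample of this beat
  idx <- i_r:min(i_end, length(lvp))
  v <- (idx - 1L) / fs - r
  p <- numeric(length(v))
  up <- v <= tau_up
  p[up] <- edp + (peak - edp) * 0.5 * (1 - cos(pi * v[up] / tau_up))
  ej <- v > tau_up & v <= sys_dur
  if (any(ej)) {
    w <- (v[ej] - tau_up) / max(sys_dur - tau_up, 1 / fs)
    p[ej] <- esp + (peak - esp) * 0.5 * (1 + cos(pi * w))
  }
  shoulder <- 0.005
  sh <- v > sys_dur & v <= sys_dur + shoulder
  p[sh] <- esp
  rel <- v > sys_dur + shoulder
  if (any(rel)) {
    d_total <- (rn - r) - sys_dur - shoulder
    tau_rel <- min(max(0.25 * d_total, 0.03), 0.12)
    u <- v[rel] - sys_dur - shoulder
    raw <- exp(-u / tau_rel)
    # linear correction so the curve lands exactly on edp_next at beat end
    resid <- exp(-d_total / tau_rel)
    p[rel] <- edp_next + (esp - edp_next) * (raw - (u / d_total) * resid)
  }
  lvp[idx] <- p
  if (max(idx) < length(lvp)) lvp[(max(idx) + 1L):length(lvp)] <- edp_next
  lvp
}

# Choose the diastolic burst (gain, center phase) so that the fundamental of
# the MED bump train points at `frac_ts - 0.5`, i.e. the bandpassed MED
# attains its per-cycle minimum at the systole/diastole boundary. The three
# bumps share one envelope shape, so their fundamental contributions are
# `gain * exp(2i*pi*center)` up to a common factor. The burst may only carry
# positive energy inside the diastolic arc `[lo, hi]`, so for each candidate
# center the gain aligning the resultant with the boundary phase is solved
# and the center giving the deepest minimum (largest aligned amplitude) is
# kept; the gain is capped at `g_cap`.
#' @noRd
solve_diastolic_burst <- function(g1, c1, g2, c2, frac_ts, lo, hi, g_cap) {
  f_vec <- g1 * exp(2i * pi * c1) + g2 * exp(2i * pi * c2)
  theta <- 2 * pi * (frac_ts - 0.5)
  # rotate so the target direction is the positive real axis
  fr <- f_vec * exp(-1i * theta)
  if (hi <= lo) return(list(gain = 0, center = (lo + hi) / 2 %% 1))
  cand <- seq(lo, hi, length.out = 60L)
  ang <- 2 * pi * cand - theta
  g3 <- -Im(fr) / sin(ang)
  kappa <- Re(fr) + g3 * cos(ang)
  feas <- is.finite(g3) & g3 > 0 & kappa > 0
  g3c <- pmin(g3, g_cap)
  if (!any(feas)) {
    # unreachable phase: best effort, push toward the target with a capped
    # burst at whichever center maximizes the aligned component
    kap2 <- Re(fr) + g_cap * cos(ang)
    j <- which.max(kap2)
    return(list(gain = g_cap, center = cand[j] %% 1))
  }
  kap_eff <- ifelse(feas, Re(fr) + g3c * cos(ang), -Inf)
  # prefer exact alignment (g3 under the cap); among those maximize depth
  exact <- feas & g3 <= g_cap
  j <- if (any(exact)) which(exact)[which.max(kappa[exact])]
       else which.max(kap_eff)
  list(gain = g3c[j], center = cand[j] %% 1)
}

#' Simulate a complete multi-step recording with ground truth
#'
#' Convenience wrapper: [simulate_hemodynamics()] followed by
#' [render_signals()].
#'
#' @inheritParams simulate_hemodynamics
#' @inheritParams render_signals
#' @return list with elements `records` (named list of [signal_record()])
#'   and `truth` (the `ground_truth` data frame).
#' @examples
#' sim <- simulate_recording(default_protocol(step_duration = 20), seed = 7)
#' names(sim$records)
#' @export
simulate_recording <- function(protocol = default_protocol(),
                               preset = hemodynamic_preset(),
                               coupling = coupling_config(),
                               noise = noise_config(),
                               sampling_rate = 1000, seed) {
  truth <- simulate_hemodynamics(protocol, preset, coupling, seed = seed)
  records <- render_signals(truth, sampling_rate = sampling_rate,
                            noise = noise, seed = seed + 1000L)
  list(records = records, truth = truth)
}
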