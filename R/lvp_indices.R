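#' Rate of pressure change dP/dt
#'
#' Central-difference derivative of the LVP trace, scaled to mmHg/s, after
#' moving-average smoothing of the pressure with `smooth_window` samples.
#' Output has the input length (edge values replicated).
#'
#' @param lvp numeric vector (mmHg).
#' @param sampling_rate Hz.
#' @param smooth_window odd number of samples for the pre-smoothing
#'   (default 5).
#' @return numeric vector of dP/dt (mmHg/s).
#' @export
compute_dpdt <- function(lvp, sampling_rate, smooth_window = 5L) {
  smooth_window <- as.integer(smooth_window)
  assert_that(smooth_window %% 2L == 1L, "smooth_window must be odd")
  if (length(lvp) < max(smooth_window, 3L)) {
    stop_phonopress("LVP trace shorter than the smoothing window",
                    "phonopress_insufficient_data_error")
  }
  p <- moving_average(lvp, smooth_window)
  n <- length(p)
  d <- numeric(n)
  d[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) * sampling_rate / 2
  d[1L] <- d[2L]
  d[n] <- d[n - 1L]
  d
}

#' Per-beat pressure indices from the invasive LVP channel
#'
#' For every valid beat of the segmentation:
#' \itemize{
#' \item `edp` -- LVP at the R-peak instant (end-diastole approximation);
#' \item `dpdtmax` -- maximum of [compute_dpdt()] over the systolic
#'   interval `[onset, boundary)`;
#' \item `esp` -- LVP at the instant of the minimum of dP/dt within the
#'   whole beat (end-systole approximation).
#' }
#' Invalid beats are omitted. The fiducial conventions are the standard
#' catheterization surrogates; they use the LVP channel only, independent
#' of the MED-derived boundary except for the systolic search window.
#'
#' @param lvp numeric LVP vector (mmHg).
#' @param seg a `beat_segmentation` from [segment_beats()].
#' @param sampling_rate Hz.
#' @param smooth_window passed to [compute_dpdt()].
#' @return a `pressure_indices` data frame: `beat`, `edp`, `esp`,
#'   `dpdtmax`, and fiducial times `edp_time`, `esp_time`, `dpdtmax_time`
#'   (seconds from the record start).
#' @export
extract_pressure_indices <- function(lvp, seg, sampling_rate,
                                     smooth_window = 5L) {
  beats <- seg$beats[seg$beats$valid, , drop = FALSE]
  if (nrow(beats) == 0L) {
    warning("no valid beats; returning empty pressure indices")
    return(empty_pressure_indices())
  }
  dpdt <- compute_dpdt(lvp, sampling_rate, smooth_window)
  fs <- sampling_rate
  n <- nrow(beats)
  out <- data.frame(
    beat = beats$beat,
    edp = NA_real_, esp = NA_real_, dpdtmax = NA_real_,
    edp_time = NA_real_, esp_time = NA_real_, dpdtmax_time = NA_real_
  )
  for (k in seq_len(n)) {
    on <- beats$onset[k]; bd <- beats$boundary[k]; en <- beats$end[k]
    out$edp[k] <- lvp[on]
    out$edp_time[k] <- (on - 1L) / fs
    sys_idx <- on:(bd - 1L)
    j <- sys_idx[which.max(dpdt[sys_idx])]
    out$dpdtmax[k] <- dpdt[j]
    out$dpdtmax_time[k] <- (j - 1L) / fs
    beat_idx <- on:(en - 1L)
    j2 <- beat_idx[which.min(dpdt[beat_idx])]
    out$esp[k] <- lvp[j2]
    out$esp_time[k] <- (j2 - 1L) / fs
  }
  structure(out, class = c("pressure_indices", "data.frame"))
}

#' @noRd
empty_pressure_indices <- function() {
  structure(
    data.frame(beat = integer(0), edp = numeric(0), esp = numeric(0),
               dpdtmax = numeric(0), edp_time = numeric(0),
               esp_time = numeric(0), dpdtmax_time = numeric(0)),
    class = c("pressure_indices", "data.frame")
  )
}
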