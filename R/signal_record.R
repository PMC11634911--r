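#' Synchronized multichannel physiological recording
#'
#' A `signal_record` holds a set of synchronized channels sampled at a common
#' rate. The canonical channels are `ECG` (V), `LVP` (mmHg, invasive
#' left-ventricular pressure), `MIC` (mmHg, phonocardiogram) and `POX` (mmHg,
#' pulse-oximetry plethysmogram). `LVP` is optional: it is only needed when
#' ground-truth pressure indices are to be extracted; a prediction-only
#' record must still carry `ECG`, `MIC` and `POX`.
#'
#' @param channels named list of equal-length numeric vectors; names from
#'   `ECG`, `LVP`, `MIC`, `POX`.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param step_label label of the pacing step (e.g. `"spontaneous"`,
#'   `"100bpm"`).
#' @param subject_label free-text subject identifier.
#' @param start_time time of the first sample in seconds.
#' @return an object of class `signal_record`.
#' @examples
#' rec <- signal_record(
#'   channels = list(ECG = sin(1:100 / 5), MIC = cos(1:100 / 7),
#'                   POX = sin(1:100 / 9)),
#'   sampling_rate = 100
#' )
#' validate_record(rec)
#' @export
signal_record <- function(channels, sampling_rate, step_label = "unknown",
                          subject_label = "unknown", start_time = 0) {
  rec <- structure(
    list(
      channels = lapply(channels, as.numeric),
      sampling_rate = as.numeric(sampling_rate),
      step_label = as.character(step_label),
      subject_label = as.character(subject_label),
      start_time = as.numeric(start_time)
    ),
    class = "signal_record"
  )
  issues <- validate_record(rec, check_finite = FALSE)
  structural <- issues[vapply(issues, function(i) i$rule != "nonfinite_sample",
                              logical(1))]
  if (length(structural) > 0L) {
    stop_phonopress(
      paste0("invalid signal_record: ",
             paste(vapply(structural, function(i) i$message, character(1)),
                   collapse = "; ")),
      "phonopress_structure_error"
    )
  }
  rec
}

CANONICAL_CHANNELS <- c("ECG", "LVP", "MIC", "POX")
MANDATORY_CHANNELS <- c("ECG", "MIC", "POX")

#' Number of samples and duration of a record
#' @param record a `signal_record`.
#' @return `record_length`: samples per channel; `record_duration`: seconds.
#' @export
record_length <- function(record) {
  if (length(record$channels) == 0L) return(0L)
  length(record$channels[[1L]])
}

#' @rdname record_length
#' @export
record_duration <- function(record) record_length(record) / record$sampling_rate

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf(
    "<signal_record> %s / %s: %d samples @ %g Hz (%.2f s), channels: %s\n",
    x$subject_label, x$step_label, record_length(x), x$sampling_rate,
    record_duration(x), paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' Validate a recording against the data-model invariants
#'
#' Always returns a report (never throws). Checks: channel names are
#' canonical, all channels share one length >= 1, the mandatory channel set
#' \{ECG, MIC, POX\} is present, the sampling rate is positive, and every
#' sample is finite. Each issue names the channel, the offending sample range
#' and the rule violated.
#'
#' @param record a `signal_record` (or a bare list with the same fields).
#' @param check_finite also scan samples for NaN/Inf/NA (default `TRUE`).
#' @return list of issue descriptors (empty list when the record is clean);
#'   each issue has fields `channel`, `samples`, `rule`, `message`.
#' @export
validate_record <- function(record, check_finite = TRUE) {
  issues <- list()
  add <- function(channel, samples, rule, message) {
    issues[[length(issues) + 1L]] <<- list(
      channel = channel, samples = samples, rule = rule, message = message
    )
  }
  if (!is.numeric(record$sampling_rate) || length(record$sampling_rate) != 1L ||
      !is.finite(record$sampling_rate) || record$sampling_rate <= 0) {
    add(NA_character_, NULL, "nonpositive_sampling_rate",
        "nonpositive sampling rate")
  }
  ch <- record$channels
  if (length(ch) == 0L) {
    add(NA_character_, NULL, "empty_record", "record has no channels")
    return(issues)
  }
  bad_names <- setdiff(names(ch), CANONICAL_CHANNELS)
  for (nm in bad_names) {
    add(nm, NULL, "unknown_channel",
        sprintf("unknown channel '%s'", nm))
  }
  missing <- setdiff(MANDATORY_CHANNELS, names(ch))
  for (nm in missing) {
    add(nm, NULL, "missing_channel",
        sprintf("mandatory channel '%s' missing", nm))
  }
  lens <- vapply(ch, length, integer(1))
  if (length(unique(lens)) > 1L) {
    add(NA_character_, NULL, "length_mismatch",
        sprintf("channel lengths differ: %s",
                paste(sprintf("%s=%d", names(lens), lens), collapse = ", ")))
  }
  if (any(lens < 1L)) {
    add(names(lens)[lens < 1L][1L], NULL, "empty_channel",
        "channel of length 0")
  }
  if (check_finite) {
    for (nm in names(ch)) {
      bad <- which(!is.finite(ch[[nm]]))
      if (length(bad) > 0L) {
        add(nm, range(bad), "nonfinite_sample",
            sprintf("channel '%s' has %d non-finite sample(s) in [%d, %d]",
                    nm, length(bad), min(bad), max(bad)))
      }
    }
  }
  issues
}
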