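#' Read a multichannel recording from disk
#'
#' Supports two on-disk formats:
#' \describe{
#'   \item{csv}{comma-separated values, one header row of channel names,
#'     optional leading `#`-prefixed metadata lines (`# fs=<Hz>`,
#'     `# step=<label>`, `# subject=<label>`). A `time` column is optional
#'     and, when present, must be consistent with `fs` to within 1e-6 s.}
#'   \item{edf}{European Data Format; channel labels are matched onto the
#'     canonical names case-insensitively.}
#' }
#' Unknown extra columns are ignored with a warning. The sampling rate is
#' taken from the file metadata.
#'
#' @param path file to read.
#' @param format_hint `"csv"`, `"edf"` or `"auto"` (by file extension).
#' @return a validated [signal_record()].
#' @export
read_record <- function(path, format_hint = c("auto", "csv", "edf")) {
  format_hint <- match.arg(format_hint)
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              "phonopress_io_error")
  fmt <- if (format_hint == "auto") {
    switch(tolower(tools::file_ext(path)), edf = "edf", "csv")
  } else format_hint
  if (fmt == "edf") read_record_edf(path) else read_record_csv(path)
}

#' Write a recording to disk
#'
#' `format = "csv"` and `"edf"` write files that [read_record()] can read
#' back; CSV output is byte-deterministic for identical inputs. CSV restores
#' the channels exactly (values are printed at full double precision); EDF is
#' a 16-bit integer format, so a round trip is exact only to its quantization
#' step (channel range / 2^16).
#'
#' `format = "wav_mic"` exports only the MIC channel as a float32 WAV file,
#' rescaled to full-scale amplitude; the scale factor (the original peak
#' absolute amplitude in mmHg) is recorded in a JSON sidecar
#' (`<path>.json`).
#'
#' @param record a valid [signal_record()].
#' @param path output file path.
#' @param format one of `"csv"`, `"edf"`, `"wav_mic"`.
#' @return the output path, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "edf", "wav_mic")) {
  format <- match.arg(format)
  assert_that(inherits(record, "signal_record"), "not a signal_record",
              "phonopress_structure_error")
  assert_that(record_length(record) >= 1L, "empty record",
              "phonopress_structure_error")
  switch(format,
    csv = write_record_csv(record, path),
    edf = write_record_edf(record, path),
    wav_mic = write_record_wav_mic(record, path)
  )
  invisible(path)
}

#' @noRd
read_record_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)\\s*$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  assert_that(length(body) >= 2L, "CSV has no data rows",
              "phonopress_structure_error")
  n_header <- length(strsplit(body[1L], ",", fixed = TRUE)[[1L]])
  n_fields <- utils::count.fields(textConnection(body), sep = ",")
  if (length(unique(n_fields)) > 1L) {
    stop_phonopress(
      sprintf("inconsistent column counts: header has %d, row %d has %d",
              n_header, which(n_fields != n_header)[1L] - 1L,
              n_fields[n_fields != n_header][1L]),
      "phonopress_structure_error"
    )
  }
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        colClasses = "character", check.names = FALSE)
  cols <- list()
  for (nm in names(df)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !(df[[nm]] %in% c("NA", "NaN", "")))
    if (length(bad) > 0L) {
      stop_phonopress(
        sprintf("non-numeric value '%s' in column '%s' at data row %d",
                df[[nm]][bad[1L]], nm, bad[1L]),
        "phonopress_parse_error"
      )
    }
    cols[[nm]] <- v
  }
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs) else NA_real_
  time_col <- NULL
  if ("time" %in% names(cols)) {
    time_col <- cols$time
    cols$time <- NULL
    if (is.na(fs) && length(time_col) >= 2L) {
      fs <- 1 / stats::median(diff(time_col))
    }
  }
  assert_that(is_scalar_number(fs) && fs > 0,
              "sampling rate not found (no '# fs=' metadata or time column)",
              "phonopress_structure_error")
  if (!is.null(time_col) && length(time_col) >= 2L) {
    expected <- time_col[1L] + (seq_along(time_col) - 1L) / fs
    assert_that(max(abs(time_col - expected)) <= 1e-6,
                "time column inconsistent with sampling rate fs",
                "phonopress_structure_error")
  }
  known <- intersect(names(cols), CANONICAL_CHANNELS)
  extra <- setdiff(names(cols), CANONICAL_CHANNELS)
  if (length(extra) > 0L) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  for (nm in MANDATORY_CHANNELS) {
    if (!nm %in% known) {
      stop_phonopress(sprintf("mandatory channel '%s' missing from %s",
                              nm, path),
                      "phonopress_channel_missing_error")
    }
  }
  signal_record(
    channels = cols[known],
    sampling_rate = fs,
    step_label = if (!is.null(meta$step)) meta$step else "unknown",
    subject_label = if (!is.null(meta$subject)) meta$subject else "unknown",
    start_time = if (!is.null(time_col)) time_col[1L] else 0
  )
}

#' @noRd
write_record_csv <- function(record, path) {
  n <- record_length(record)
  tt <- record$start_time + (seq_len(n) - 1L) / record$sampling_rate
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%s", format(record$sampling_rate, digits = 17)),
    sprintf("# step=%s", record$step_label),
    sprintf("# subject=%s", record$subject_label),
    paste(c("time", names(record$channels)), collapse = ",")
  ), con)
  cols <- c(list(format(tt, digits = 17, trim = TRUE, scientific = FALSE)),
            lapply(record$channels, function(x) {
              formatC(x, digits = 17, format = "g")
            }))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  path
}

#' @noRd
write_record_wav_mic <- function(record, path) {
  assert_that("MIC" %in% names(record$channels),
              "record has no MIC channel", "phonopress_channel_missing_error")
  x <- record$channels$MIC
  peak <- max(abs(x))
  scale <- if (peak > 0) peak else 1
  write_wav(x / scale, record$sampling_rate, path)
  jsonlite::write_json(
    list(scale_factor_mmHg = scale,
         sampling_rate_hz = record$sampling_rate,
         channel = "MIC",
         step_label = record$step_label,
         subject_label = record$subject_label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  path
}
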