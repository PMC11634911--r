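# Minimal EDF (European Data Format) writer/reader for synchronized
# physiological channels. EDF stores 16-bit integers with per-signal
# physical/digital calibration, so values round-trip to within one
# quantization step (physical range / 2^16). The whole recording is written
# as a single data record whose duration is the record duration; the reader
# recovers the sampling rate as samples-per-record / record-duration.
#
# No EDF package ships with this toolchain, hence the self-contained
# implementation; it writes standard headers readable by common EDF tools.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = "-")
}

#' @noRd
write_record_edf <- function(record, path) {
  ch <- record$channels
  ns <- length(ch)
  n <- record_length(record)
  fs <- record$sampling_rate
  duration <- n / fs
  dur_str <- edf_pad(formatC(duration, format = "g", digits = 7), 8)
  dmin <- -32768L; dmax <- 32767L
  pmin_str <- pmax_str <- character(ns)
  digital <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- ch[[i]]
    lo <- min(x); hi <- max(x)
    if (hi <= lo) hi <- lo + 1
    span <- hi - lo
    lo <- lo - 0.002 * span
    hi <- hi + 0.002 * span
    pmin_str[i] <- edf_pad(formatC(lo, format = "g", digits = 6), 8)
    pmax_str[i] <- edf_pad(formatC(hi, format = "g", digits = 6), 8)
    # quantize against the values as written, so the reader's reconstruction
    # matches to one digital step
    lo_w <- as.numeric(pmin_str[i]); hi_w <- as.numeric(pmax_str[i])
    d <- round((x - lo_w) / (hi_w - lo_w) * (dmax - dmin)) + dmin
    digital[[i]] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  header_bytes <- 256L + 256L * ns
  rec_id <- sprintf("step=%s subject=%s start=%.6f",
                    record$step_label, record$subject_label,
                    record$start_time)
  con <- file(path, open = "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put("X X X X", 80)
  put(rec_id, 80)
  put("01.01.00", 8)
  put("00.00.00", 8)
  put(as.character(header_bytes), 8)
  put("", 44)
  put("1", 8)                      # one data record
  put(dur_str, 8)
  put(as.character(ns), 4)
  for (nm in names(ch)) put(nm, 16)
  for (i in seq_len(ns)) put("", 80)                 # transducer
  for (nm in names(ch)) put(if (nm == "ECG") "V" else "mmHg", 8)
  for (i in seq_len(ns)) put(pmin_str[i], 8)
  for (i in seq_len(ns)) put(pmax_str[i], 8)
  for (i in seq_len(ns)) put(as.character(dmin), 8)
  for (i in seq_len(ns)) put(as.character(dmax), 8)
  for (i in seq_len(ns)) put("", 80)                 # prefiltering
  for (i in seq_len(ns)) put(as.character(n), 8)     # samples per record
  for (i in seq_len(ns)) put("", 32)
  for (i in seq_len(ns)) {
    writeBin(digital[[i]], con, size = 2L, endian = "little")
  }
  path
}

#' @noRd
read_record_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  get <- function(w) {
    raw <- readBin(con, "raw", n = w)
    assert_that(length(raw) == w, "truncated EDF header",
                "phonopress_structure_error")
    trimws(rawToChar(raw))
  }
  get(8)                              # version
  get(80)                             # patient id
  rec_id <- get(80)
  get(8); get(8)                      # date, time
  get(8)                              # header bytes
  get(44)
  n_records <- as.integer(get(8))
  duration <- as.numeric(get(8))
  ns <- as.integer(get(4))
  assert_that(is.finite(n_records) && n_records >= 1L && ns >= 1L,
              "malformed EDF header", "phonopress_structure_error")
  labels <- vapply(seq_len(ns), function(i) get(16), character(1))
  for (i in seq_len(ns)) get(80)
  for (i in seq_len(ns)) get(8)       # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(get(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(get(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(get(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(get(8)), numeric(1))
  for (i in seq_len(ns)) get(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(get(8)), integer(1))
  for (i in seq_len(ns)) get(32)
  chans <- stats::setNames(
    lapply(seq_len(ns), function(i) numeric(0)), labels)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      x <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      chans[[i]] <- c(chans[[i]], x)
    }
  }
  fs <- spr[1L] / (duration / 1)      # samples per record over record length
  # canonicalize labels case-insensitively
  canon <- CANONICAL_CHANNELS[match(toupper(labels), CANONICAL_CHANNELS)]
  keep <- !is.na(canon)
  if (any(!keep)) {
    warning(sprintf("ignoring unknown EDF channel(s): %s",
                    paste(labels[!keep], collapse = ", ")))
  }
  chans <- stats::setNames(chans[keep], canon[keep])
  for (nm in MANDATORY_CHANNELS) {
    if (!nm %in% names(chans)) {
      stop_phonopress(sprintf("mandatory channel '%s' missing from %s",
                              nm, path),
                      "phonopress_channel_missing_error")
    }
  }
  meta <- list(step = "unknown", subject = "unknown", start = 0)
  for (kv in strsplit(rec_id, "\\s+")[[1]]) {
    p <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(p) == 2L) meta[[p[1]]] <- p[2]
  }
  signal_record(
    channels = chans, sampling_rate = fs,
    step_label = meta$step, subject_label = meta$subject,
    start_time = as.numeric(meta$start)
  )
}
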