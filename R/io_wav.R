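# Minimal RIFF/WAVE writer and reader (IEEE float32, mono), used for the
# phonocardiogram export. Float samples keep the rescaled waveform exact;
# the physical scale factor travels in the JSON sidecar written by
# write_record(format = "wav_mic").

#' @noRd
write_wav <- function(x, sampling_rate, path) {
  n <- length(x)
  byte_rate <- as.integer(sampling_rate * 4)
  data_bytes <- n * 4L
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(3L, con, size = 2L, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(round(sampling_rate)), con, size = 4L, endian = "little")
  writeBin(byte_rate, con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")   # block align
  writeBin(32L, con, size = 2L, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4L, endian = "little")
  writeBin(as.numeric(x), con, size = 4L, endian = "little")
  path
}

#' @noRd
read_wav <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 4))
  assert_that(hdr == "RIFF", "not a RIFF file", "phonopress_parse_error")
  readBin(con, "integer", 1, size = 4, endian = "little")
  assert_that(rawToChar(readBin(con, "raw", 4)) == "WAVE",
              "not a WAVE file", "phonopress_parse_error")
  fmt <- NULL; fs <- NA_real_; bits <- NA_integer_; audio_fmt <- NA_integer_
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (audio_fmt == 3L) {
        x <- readBin(con, "numeric", n = size %/% 4L, size = 4L,
                     endian = "little")
      } else {
        x <- readBin(con, "integer", n = size %/% 2L, size = 2L,
                     signed = TRUE, endian = "little") / 32768
      }
      return(list(samples = x, sampling_rate = fs, bits = bits))
    } else {
      readBin(con, "raw", size)
    }
  }
  stop_phonopress("no data chunk in WAV file", "phonopress_parse_error")
}
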