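# Minimal RIFF/WAVE PCM reader and writer. Only 16-bit integer PCM is
# supported; that is the sensors' native format and the only one the
# pipeline accepts.

#' Read a 16-bit PCM WAV file
#'
#' @param path path to a RIFF/WAVE file containing uncompressed 16-bit PCM.
#' @return a list with `samples` (integer vector, interleaved if multichannel),
#'   `fs` (sampling rate, Hz) and `n_channels`.
#' @keywords internal
read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("not a RIFF file: ", path, call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
      fmt <- list(format = audio_format, n_channels = n_channels,
                  fs = fs, bits = bits)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size, size = 2, signed = TRUE,
                         endian = "little")
      if (size %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip unknown chunk (word-aligned)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(fmt) || is.null(samples)) {
    stop("malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$format != 1L || fmt$bits != 16L) {
    stop("unsupported WAV format: need 16-bit PCM, got format tag ",
         fmt$format, " with ", fmt$bits, " bits", call. = FALSE)
  }
  list(samples = samples, fs = fmt$fs, n_channels = fmt$n_channels)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples integer vector in \[-32768, 32767\].
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @keywords internal
write_wav_pcm16 <- function(samples, fs, path) {
  samples <- as.integer(round(samples))
  stopifnot(all(samples >= -32768L & samples <= 32767L))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(1L, con, size = 2, endian = "little")      # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # block align
  writeBin(16L, con, size = 2, endian = "little")     # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}
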