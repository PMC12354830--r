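# ---- Recording ----------------------------------------------------------

#' Construct a sensor recording
#'
#' A recording is one sensor minute (nominally): a vector of 16-bit integer
#' amplitudes, a sampling rate, a sensor identifier and a UTC start time.
#' Other lengths than 60 s are accepted; sub-second tails are handled at
#' segmentation time.
#'
#' @param samples integer (or integer-valued numeric) vector of amplitudes in
#'   \[-32768, 32767\].
#' @param fs sampling rate in Hz (default 4000, the sensors' rate).
#' @param sensor_id opaque sensor identifier string.
#' @param start_time recording start, `POSIXct` (UTC) or a string parseable as
#'   ISO 8601.
#' @return an object of class `recording`.
#' @export
recording <- function(samples, fs = 4000, sensor_id = "unknown",
                      start_time = as.POSIXct("1970-01-01", tz = "UTC")) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  samples <- as.integer(round(samples))
  if (any(samples < -32768L | samples > 32767L, na.rm = TRUE)) {
    stop("samples outside the 16-bit range [-32768, 32767]", call. = FALSE)
  }
  if (is.character(start_time)) {
    start_time <- parse_iso8601(start_time)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         sensor_id = as.character(sensor_id), start_time = start_time),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> sensor %s, %.1f s @ %g Hz, start %s\n",
              x$sensor_id, length(x$samples) / x$fs, x$fs,
              format(x$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")))
  invisible(x)
}

parse_iso8601 <- function(x) {
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H%M%OS", "%Y%m%dT%H%M%S",
                                   "%Y-%m-%d"))
  out
}

#' Read a recording from a 16-bit PCM mono WAV file
#'
#' Sensor id and start time are parsed from the filename, which by
#' convention is `<sensor_id>_<ISO8601>.wav` (e.g.
#' `efs042_2024-06-17T041500Z.wav`). A filename that does not match yields
#' sensor id equal to the file stem and the Unix epoch as start time.
#'
#' @param path WAV file path.
#' @param filename_pattern regex with two capture groups (sensor id,
#'   timestamp) applied to the file stem.
#' @return a [recording].
#' @export
read_recording <- function(path,
                           filename_pattern = "^(.+)_([0-9TZ:.+-]+)$") {
  wav <- read_wav_pcm16(path)
  if (wav$n_channels != 1L) {
    stop("unsupported channel count: expected mono, got ",
         wav$n_channels, " channels", call. = FALSE)
  }
  stem <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  sensor_id <- stem
  start_time <- as.POSIXct(0, origin = "1970-01-01", tz = "UTC")
  m <- regmatches(stem, regexec(filename_pattern, stem))[[1]]
  if (length(m) == 3) {
    sensor_id <- m[2]
    ts <- tryCatch(parse_iso8601(m[3]), error = function(e) NA)
    if (!is.na(ts)) start_time <- ts
  }
  recording(wav$samples, fs = wav$fs, sensor_id = sensor_id,
            start_time = start_time)
}

#' Write a recording to a 16-bit PCM mono WAV file
#'
#' @param rec a [recording].
#' @param path output path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  write_wav_pcm16(rec$samples, rec$fs, path)
}

# ---- Segmentation -------------------------------------------------------

#' Split a recording into contiguous 1-second segments
#'
#' Segments are half-open: segment `i` (0-based) covers seconds
#' \[i, i+1) from the recording start. A trailing partial second is
#' discarded. Samples are normalized to \[-1, 1) by division by 32768,
#' the scale on which all downstream DSP (and augmentation amplitudes)
#' operate.
#'
#' @param rec a [recording].
#' @return a list of `segment` objects (possibly empty); each has `samples`
#'   (normalized doubles of length `fs`), `index` (0-based), `fs`,
#'   `sensor_id`, `start_time`.
#' @export
segment_signal <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  n_full <- floor(length(rec$samples) / fs)
  if (n_full < 1) return(list())
  x <- rec$samples / 32768
  lapply(seq_len(n_full) - 1L, function(i) {
    structure(
      list(samples = x[(i * fs + 1):((i + 1) * fs)], index = i, fs = fs,
           sensor_id = rec$sensor_id, start_time = rec$start_time),
      class = "segment"
    )
  })
}

# ---- Spectrogram --------------------------------------------------------

hann_window <- function(n) {
  # periodic Hann, the STFT convention
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

#' Short-time Fourier transform magnitudes
#'
#' Centered (reflect-padded) STFT with FFT length `n_fft`, hop `hop` and a
#' periodic Hann window. For a 4000-sample segment with the defaults the
#' result is the pipeline's canonical 129 x 32 magnitude matrix: 129
#' frequency bins (0 to Nyquist, 15.625 Hz apart) by 32 frames (32 ms
#' apart). Raw magnitudes are stored; consumers (the CNN detector) apply
#' their own log compression.
#'
#' @param x numeric vector (a segment's normalized samples) or a `segment`.
#' @param n_fft FFT length (default 256).
#' @param hop hop length in samples (default 128).
#' @return a `spectrogram`: numeric matrix (bins x frames) with attributes
#'   `bin_hz` and `frame_s`.
#' @export
spectrogram <- function(x, n_fft = 256L, hop = 128L) {
  fs <- 4000
  if (inherits(x, "segment")) {
    fs <- x$fs
    x <- x$samples
  }
  if (length(x) != 4000L) {
    stop("spectrogram() expects a 4000-sample (1 s @ 4 kHz) segment, got ",
         length(x), " samples", call. = FALSE)
  }
  n <- length(x)
  half <- n_fft %/% 2L
  # reflect padding (no repeated edge sample)
  left <- rev(x[2:(half + 1)])
  right <- rev(x[(n - half):(n - 1)])
  xp <- c(left, x, right)
  n_frames <- 1L + n %/% hop
  w <- hann_window(n_fft)
  frames <- vapply(seq_len(n_frames) - 1L, function(t) {
    xp[(t * hop + 1):(t * hop + n_fft)] * w
  }, numeric(n_fft))
  spec <- abs(stats::mvfft(frames))[seq_len(half + 1L), , drop = FALSE]
  structure(spec, bin_hz = fs / n_fft, frame_s = hop / fs,
            class = c("spectrogram", "matrix", "array"))
}
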