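test_that("WAV round trip preserves samples, rate and metadata parsing", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "efs042_2024-06-17T041500Z.wav")
  set.seed(1)
  samples <- sample(-32768:32767, 8000, replace = TRUE)
  write_recording(recording(samples, sensor_id = "efs042"), path)
  rec <- read_recording(path)
  expect_identical(rec$samples, as.integer(samples))
  expect_equal(rec$fs, 4000)
  expect_equal(rec$sensor_id, "efs042")
  expect_equal(format(rec$start_time, "%Y-%m-%d %H:%M", tz = "UTC"),
               "2024-06-17 04:15")
})

test_that("reader accepts any length but rejects non-mono / non-16-bit", {
  tmp <- withr::local_tempdir()
  p60 <- file.path(tmp, "a_2024-01-01T000000Z.wav")
  write_recording(recording(rep(0L, 240000)), p60)
  expect_length(read_recording(p60)$samples, 240000)
  p90 <- file.path(tmp, "b_2024-01-01T000000Z.wav")
  write_recording(recording(rep(0L, 360000)), p90)
  expect_length(read_recording(p90)$samples, 360000)
  # hand-build a stereo WAV header
  pst <- file.path(tmp, "stereo.wav")
  con <- file(pst, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(44L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")      # stereo
  writeBin(4000L, con, size = 4, endian = "little")
  writeBin(16000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(8L, con, size = 4, endian = "little")
  writeBin(rep(0L, 4), con, size = 2, endian = "little")
  close(con)
  expect_error(read_recording(pst), "mono")
})

test_that("recording constructor enforces the 16-bit range and fs > 0", {
  expect_error(recording(c(0, 40000)), "16-bit")
  expect_error(recording(0, fs = 0), "positive")
})

test_that("segmentation yields contiguous whole seconds, tail discarded", {
  rec <- recording(seq_len(240000) %% 1000)
  expect_length(segment_signal(rec), 60)
  rec2 <- recording(seq_len(6500) %% 1000)
  segs <- segment_signal(rec2)
  expect_length(segs, 1)
  expect_length(segs[[1]]$samples, 4000)
  expect_length(segment_signal(recording(seq_len(3999) %% 1000)), 0)
})

test_that("concatenated segments reproduce the first floor(N/fs)*fs samples", {
  set.seed(3)
  x <- sample(-32768:32767, 9500, replace = TRUE)
  rec <- recording(x)
  segs <- segment_signal(rec)
  expect_length(segs, 2)
  recon <- unlist(lapply(segs, `[[`, "samples")) * 32768
  expect_equal(recon, as.numeric(x[1:8000]))
  expect_equal(vapply(segs, `[[`, numeric(1), "index"), c(0, 1))
})

test_that("spectrogram is exactly 129 x 32 with non-negative magnitudes", {
  set.seed(7)
  for (i in 1:5) {
    sp <- spectrogram(rnorm(4000))
    expect_identical(dim(sp), c(129L, 32L))
    expect_true(all(sp >= 0))
  }
  expect_error(spectrogram(rnorm(4001)), "4000-sample")
})

test_that("spectrogram: zero input and amplitude scaling behave linearly", {
  expect_true(all(spectrogram(rep(0, 4000)) == 0))
  set.seed(11)
  x <- rnorm(4000)
  s1 <- spectrogram(x); s2 <- spectrogram(2 * x)
  expect_equal(unclass(s2), 2 * unclass(s1), tolerance = 1e-12)
  expect_equal(sum(s2^2) / sum(s1^2), 4, tolerance = 1e-12)
})

test_that("spectrogram localizes a pure tone in the right frequency bin", {
  x <- sin(2 * pi * 250 * (0:3999) / 4000)
  sp <- spectrogram(x)
  # 250 Hz / (4000/256) Hz per bin = bin 16 (0-based), row 17
  expect_equal(unname(which.max(rowMeans(sp))), 17)
  expect_equal(attr(sp, "bin_hz"), 4000 / 256)
  expect_equal(attr(sp, "frame_s"), 128 / 4000)
})
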