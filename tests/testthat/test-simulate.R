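test_that("synthesis is a pure function of (spec, seed)", {
  sc <- scene_spec(3, list(insect_event_spec(210, 1, 1)), seed = 5)
  a <- synth_recording(sc)
  b <- synth_recording(sc)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  c <- synth_recording(scene_spec(3, list(insect_event_spec(210, 1, 1)),
                                  seed = 6))
  expect_false(identical(a$recording$samples, c$recording$samples))
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(synth_recording(sc)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a 210 Hz event shows harmonic ridges at 210/420/630 Hz", {
  sc <- scene_spec(3, list(insect_event_spec(210, 1, 1, peak_amp = 0.1,
                                             envelope = "flat")),
                   noise_sd = 0.001, seed = 9)
  out <- synth_recording(sc)
  seg <- segment_signal(out$recording)[[2]]
  sp <- unclass(spectrogram(seg))
  prof <- rowMeans(sp)
  bin_hz <- 4000 / 256
  ridge_bins <- round(c(210, 420, 630) / bin_hz) + 1
  background <- median(prof)
  for (b in ridge_bins) {
    expect_gt(max(prof[(b - 1):(b + 1)]), 10 * background)
  }
})

test_that("WAV export of a synthetic scene is byte-stable for a fixed seed", {
  tmp <- withr::local_tempdir()
  sc <- scene_spec(2, list(insect_event_spec(160, 0.5, 1)), seed = 4)
  p1 <- file.path(tmp, "a.wav"); p2 <- file.path(tmp, "b.wav")
  write_recording(synth_recording(sc)$recording, p1)
  write_recording(synth_recording(sc)$recording, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("clipping scenes are peak-normalized with a warning", {
  sc <- scene_spec(2, list(insect_event_spec(160, 0.5, 1, peak_amp = 0.9),
                           insect_event_spec(165, 0.5, 1, peak_amp = 0.9)),
                   noise_sd = 0.05, seed = 3)
  expect_warning(out <- synth_recording(sc), "clip")
  expect_true(all(abs(out$recording$samples) <= 32767))
})

test_that("events must fit inside the scene", {
  expect_error(scene_spec(2, list(insect_event_spec(160, 1.5, 1))), "fit")
})

test_that("dataset splits are sensor-disjoint with curation rules applied", {
  ds <- synth_dataset(20, 40, seed = 13)
  splits <- split(ds$manifest$sensor_id, ds$manifest$split)
  expect_length(intersect(splits$train, splits$val), 0)
  expect_length(intersect(splits$train, splits$test), 0)
  expect_length(intersect(splits$val, splits$test), 0)
  expect_equal(sum(ds$manifest$label == 1), 20)
  expect_equal(sum(ds$manifest$label == 0), 40)
  expect_true(all(vapply(ds$train$segments, length, integer(1)) == 4000))
  # reproducible
  ds2 <- synth_dataset(20, 40, seed = 13)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$train$segments[[1]], ds2$train$segments[[1]])
})

test_that("short events are padded to 1 s, long ones rounded down", {
  # a single 0.4 s event -> exactly one insect segment (symmetric padding)
  short <- synth_dataset(1, 1, seed = 21, duration_range = c(0.4, 0.4))
  expect_equal(sum(short$manifest$label == 1), 1)
  # 2.7 s events -> floor(2.7) = 2 whole-second segments each
  long <- synth_dataset(2, 1, seed = 22, duration_range = c(2.7, 2.7))
  expect_equal(sum(long$manifest$label == 1), 2)
})

test_that("reference-table generator reproduces the published region shape", {
  df <- synth_reference_table(seed = 31)
  expect_equal(sum(df$wbf_hz <= 240), 360)
  expect_equal(sum(df$wbf_hz > 240 & df$wbf_hz <= 340), 14)
  expect_equal(sum(df$wbf_hz > 340), 33)
  expect_true(any(df$wbf_hz == 480))
  minimal <- synth_reference_table(0, 0, 1, seed = 32)
  expect_equal(nrow(minimal), 1)
  expect_equal(minimal$wbf_hz, 480)
  expect_identical(synth_reference_table(seed = 31), df)
})

test_that("mains interference shifts recovered WBF by < 1 Hz after cancellation", {
  model <- get_test_model()
  ev <- list(insect_event_spec(212, 2, 3, peak_amp = 0.08))
  clean <- synth_recording(scene_spec(8, ev, seed = 51, noise_sd = 0.002))
  noisy <- synth_recording(scene_spec(8, ev, seed = 51, noise_sd = 0.002,
                                      mains_hz = 50, mains_amp = 0.05))
  r1 <- process_recording(clean$recording, model)
  r2 <- process_recording(noisy$recording, model)
  expect_true(r2$powerline$detected)
  expect_gte(nrow(r1$events), 1)
  expect_gte(nrow(r2$events), 1)
  main_mu <- function(r) r$events$mu_f0[which.max(r$events$n_segments)]
  expect_lt(abs(main_mu(r1) - main_mu(r2)), 1)
})
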