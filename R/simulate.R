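# Ground-truth signal simulator. Emulates what the electrostatic sensor
# sees: an insect pass is a harmonic stack (fundamental = wing-beat
# frequency plus geometrically decaying overtones) whose fundamental
# wobbles a few Hz on ~100 ms timescales (mean-reverting jitter) and whose
# amplitude follows an approach-retreat envelope; on top of that, optional
# mains interference (50/60 Hz plus harmonics) and broadband noise.
# All generators are pure functions of (spec, seed).

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify one simulated insect pass
#'
#' @param true_wbf nominal wing-beat frequency in Hz (20-2000).
#' @param onset_s,duration_s event placement within the scene, seconds.
#' @param peak_amp peak amplitude on the normalized \[-1, 1) scale.
#' @param wbf_jitter_sd stationary standard deviation of the WBF jitter in
#'   Hz (default 3: insect WBFs wobble by a few Hz, which is what the
#'   sigma_f0 >= 1 Hz keep-rule exploits).
#' @param jitter_tau_s correlation time of the mean-reverting
#'   (Ornstein-Uhlenbeck) jitter in seconds (default 0.1).
#' @param n_harmonics number of harmonics including the fundamental.
#' @param harmonic_decay geometric amplitude ratio between consecutive
#'   harmonics (default 0.6, mimicking observed ridge stacks).
#' @param envelope "hann" (approach-retreat) or "flat".
#' @return an `insect_event_spec` list.
#' @export
insect_event_spec <- function(true_wbf, onset_s, duration_s,
                              peak_amp = 0.05, wbf_jitter_sd = 3,
                              jitter_tau_s = 0.1, n_harmonics = 4L,
                              harmonic_decay = 0.6,
                              envelope = c("hann", "flat")) {
  stopifnot(true_wbf > 20, true_wbf < 2000, duration_s > 0, peak_amp > 0)
  structure(list(true_wbf = true_wbf, onset_s = onset_s,
                 duration_s = duration_s, peak_amp = peak_amp,
                 wbf_jitter_sd = wbf_jitter_sd,
                 jitter_tau_s = jitter_tau_s,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_decay = harmonic_decay,
                 envelope = match.arg(envelope)),
            class = "insect_event_spec")
}

#' Specify a simulated scene
#'
#' @param duration_s scene length in seconds (default 60, one sensor
#'   minute).
#' @param events list of [insect_event_spec()]s; all must fit in the
#'   scene.
#' @param mains_hz 0 (off), 50 or 60.
#' @param mains_amp amplitude of the mains fundamental (normalized scale).
#' @param mains_harmonics number of mains harmonics (amplitude 1/k decay).
#' @param noise_sd broadband Gaussian noise standard deviation.
#' @param fs sampling rate (default 4000).
#' @param sensor_id,start_time recording metadata.
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(duration_s = 60, events = list(), mains_hz = 0,
                       mains_amp = 0.05, mains_harmonics = 5L,
                       noise_sd = 0.002, fs = 4000,
                       sensor_id = "sim", start_time = "2024-06-17T04:00:00Z",
                       seed = 1L) {
  stopifnot(mains_hz %in% c(0, 50, 60))
  for (ev in events) {
    stopifnot(inherits(ev, "insect_event_spec"))
    if (ev$onset_s < 0 || ev$onset_s + ev$duration_s > duration_s) {
      stop("event does not fit in the scene", call. = FALSE)
    }
  }
  structure(list(duration_s = duration_s, events = events,
                 mains_hz = mains_hz, mains_amp = mains_amp,
                 mains_harmonics = as.integer(mains_harmonics),
                 noise_sd = noise_sd, fs = fs, sensor_id = sensor_id,
                 start_time = start_time, seed = as.integer(seed)),
            class = "scene_spec")
}

# Mean-reverting (OU) jitter around the nominal WBF, sampled on a coarse
# node grid and linearly interpolated to the sample grid.
ou_track <- function(n_samples, fs, base, sd, tau) {
  node_dt <- 0.01
  n_nodes <- max(2L, ceiling(n_samples / fs / node_dt) + 1L)
  phi <- exp(-node_dt / tau)
  eps <- stats::rnorm(n_nodes)
  f <- numeric(n_nodes)
  f[1] <- base + sd * eps[1]
  step_sd <- sd * sqrt(1 - phi^2)
  for (k in 2:n_nodes) {
    f[k] <- base + phi * (f[k - 1] - base) + step_sd * eps[k]
  }
  stats::approx(seq(0, by = node_dt, length.out = n_nodes), f,
                xout = (seq_len(n_samples) - 1) / fs, rule = 2)$y
}

synth_event_wave <- function(ev, fs) {
  n <- round(ev$duration_s * fs)
  f_inst <- ou_track(n, fs, ev$true_wbf, ev$wbf_jitter_sd, ev$jitter_tau_s)
  f_inst <- pmax(f_inst, 1)
  phase <- 2 * pi * cumsum(f_inst) / fs
  x <- numeric(n)
  for (h in seq_len(ev$n_harmonics)) {
    x <- x + ev$harmonic_decay^(h - 1) *
      sin(h * phase + stats::runif(1, 0, 2 * pi))
  }
  env <- switch(ev$envelope,
                hann = hann_window(n + 2L)[2:(n + 1L)],
                flat = rep(1, n))
  x <- x * env
  x <- x / max(abs(x)) * ev$peak_amp
  list(wave = x, realized_mu = mean(f_inst), realized_sd = stats::sd(f_inst))
}

#' Synthesize a recording with ground truth
#'
#' @param scene a [scene_spec()].
#' @return list with `recording` (a [recording]) and `truth` (data frame:
#'   `event_id`, `true_wbf`, `realized_mu_f0` (time-average of the
#'   jittered fundamental, the reference for recovery checks),
#'   `onset_s`, `duration_s`, `peak_amp`).
#' @export
synth_recording <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  # each component gets its own seed substream: toggling mains (or adding
  # an event) must not change the realization of the others, so that
  # ablation comparisons (e.g. +/- interference) are controlled
  with_seed(scene$seed, {
    fs <- scene$fs
    n <- round(scene$duration_s * fs)
    x <- stats::rnorm(n, 0, scene$noise_sd)
    if (scene$mains_hz > 0 && scene$mains_amp > 0) {
      set.seed(scene$seed %% 1000000L + 500L)
      t <- (seq_len(n) - 1) / fs
      for (k in seq_len(scene$mains_harmonics)) {
        f <- k * scene$mains_hz
        if (f >= fs / 2) break
        x <- x + scene$mains_amp / k *
          sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
    }
    truth <- data.frame(event_id = integer(), true_wbf = numeric(),
                        realized_mu_f0 = numeric(), onset_s = numeric(),
                        duration_s = numeric(), peak_amp = numeric())
    for (i in seq_along(scene$events)) {
      ev <- scene$events[[i]]
      set.seed(scene$seed %% 1000000L + 1000L + i)
      sw <- synth_event_wave(ev, fs)
      i0 <- round(ev$onset_s * fs)
      idx <- (i0 + 1):(i0 + length(sw$wave))
      x[idx] <- x[idx] + sw$wave
      truth <- rbind(truth, data.frame(
        event_id = i, true_wbf = ev$true_wbf,
        realized_mu_f0 = sw$realized_mu, onset_s = ev$onset_s,
        duration_s = ev$duration_s, peak_amp = ev$peak_amp))
    }
    peak <- max(abs(x))
    if (peak >= 1) {
      warning("synthetic scene clips; peak-normalizing to 0.99",
              call. = FALSE)
      x <- x / peak * 0.99
    }
    rec <- recording(round(x * 32767), fs = fs, sensor_id = scene$sensor_id,
                     start_time = scene$start_time)
    list(recording = rec, truth = truth)
  })
}

# draw one "interesting" non-insect segment (normalized waveform)
synth_noise_segment <- function(fs) {
  n <- fs
  sd <- exp(stats::runif(1, log(0.001), log(0.01)))
  x <- stats::rnorm(n, 0, sd)
  t <- (seq_len(n) - 1) / fs
  if (stats::runif(1) < 0.3) {                 # mains-like hum
    f0 <- sample(c(50, 60), 1)
    for (k in 1:4) {
      x <- x + stats::runif(1, 0.005, 0.05) / k *
        sin(2 * pi * k * f0 * t + stats::runif(1, 0, 2 * pi))
    }
  }
  if (stats::runif(1) < 0.3) {                 # wind rumble below 20 Hz
    x <- x + stats::runif(1, 0.01, 0.05) *
      sin(2 * pi * stats::runif(1, 2, 15) * t + stats::runif(1, 0, 2 * pi))
  }
  if (stats::runif(1) < 0.2) {                 # stable electrical tone
    x <- x + stats::runif(1, 0.005, 0.03) *
      sin(2 * pi * stats::runif(1, 80, 900) * t + stats::runif(1, 0, 2 * pi))
  }
  x
}

#' Synthesize a labeled, sensor-split CNN dataset
#'
#' Insect segments are cut from simulated passes with the dataset-curation
#' rules: passes of one second or longer contribute
#' `floor(duration)` non-overlapping whole-second segments; shorter passes
#' contribute one segment padded symmetrically with the surrounding
#' signal. Non-insect segments mix broadband noise, mains-like hum, wind
#' rumble and stable electrical tones. Segments are distributed over
#' `n_sensors` virtual sensors and split sensor-disjointly (roughly
#' 50/25/25) into train/validation/test.
#'
#' @param n_insect,n_noise segment counts per class.
#' @param n_sensors number of virtual sensors (>= 3; default 6).
#' @param seed RNG seed (the generator is a pure function of the
#'   arguments).
#' @param wbf_range range of nominal WBFs, Hz.
#' @param duration_range range of pass durations, seconds.
#' @param amp_range range of pass peak amplitudes.
#' @return list with `train`, `val`, `test` ([labeled_segments]) and
#'   `manifest` (data frame: `segment_id`, `sensor_id`, `label`, `split`,
#'   `true_wbf`).
#' @export
synth_dataset <- function(n_insect, n_noise, n_sensors = 6L, seed = 1L,
                          wbf_range = c(50, 500),
                          duration_range = c(0.3, 3),
                          amp_range = c(0.02, 0.2)) {
  stopifnot(n_insect >= 1, n_noise >= 1, n_sensors >= 3)
  with_seed(seed, {
    fs <- 4000L
    segs <- list(); labels <- integer(); wbfs <- numeric()
    while (sum(labels == 1L) < n_insect) {
      dur <- stats::runif(1, duration_range[1], duration_range[2])
      wbf <- stats::runif(1, wbf_range[1], wbf_range[2])
      scene_len <- ceiling(dur) + 2
      onset <- stats::runif(1, 0.5, scene_len - dur - 0.5)
      ev <- insect_event_spec(wbf, onset, dur,
                              peak_amp = stats::runif(1, amp_range[1],
                                                      amp_range[2]))
      sc <- scene_spec(scene_len, list(ev), noise_sd = 0.002, fs = fs,
                       seed = sample.int(.Machine$integer.max, 1))
      x <- synth_recording(sc)$recording$samples / 32768
      i0 <- round(onset * fs)
      if (dur >= 1) {
        for (k in seq_len(floor(dur))) {     # whole seconds, rounded down
          if (sum(labels == 1L) >= n_insect) break
          segs[[length(segs) + 1L]] <- x[(i0 + (k - 1) * fs + 1):(i0 + k * fs)]
          labels <- c(labels, 1L); wbfs <- c(wbfs, wbf)
        }
      } else {                               # symmetric padding to 1 s
        mid <- i0 + round(dur * fs / 2)
        start <- min(max(0L, mid - fs %/% 2L), length(x) - fs)
        segs[[length(segs) + 1L]] <- x[(start + 1):(start + fs)]
        labels <- c(labels, 1L); wbfs <- c(wbfs, wbf)
      }
    }
    for (j in seq_len(n_noise)) {
      segs[[length(segs) + 1L]] <- synth_noise_segment(fs)
      labels <- c(labels, 0L); wbfs <- c(wbfs, NA_real_)
    }
    n <- length(segs)
    sensor_ids <- sprintf("vsensor%02d", sample.int(n_sensors, n,
                                                    replace = TRUE))
    sensor_split <- rep(c("train", "val", "test"),
                        times = c(ceiling(n_sensors / 2),
                                  ceiling(n_sensors / 4),
                                  n_sensors - ceiling(n_sensors / 2) -
                                    ceiling(n_sensors / 4)))
    names(sensor_split) <- sprintf("vsensor%02d", seq_len(n_sensors))
    split <- unname(sensor_split[sensor_ids])
    manifest <- data.frame(segment_id = seq_len(n), sensor_id = sensor_ids,
                           label = labels, split = split, true_wbf = wbfs)
    subset_ls <- function(s) {
      sel <- split == s
      labeled_segments(segs[sel], labels[sel], sensor_ids[sel])
    }
    list(train = subset_ls("train"), val = subset_ls("val"),
         test = subset_ls("test"), manifest = manifest)
  })
}

#' Synthesize a reference table with the published region structure
#'
#' Entries are drawn uniformly in each region's frequency range with
#' log-normal masses (heavier taxa at low WBFs, mosquito-scale masses in
#' the sparse region); a 480 Hz entry is always included so the
#' sparse-region fallback is well defined. Defaults reproduce the
#' published table shape (360 dense, 14 less dense, 33 sparse).
#'
#' @param n_dense,n_less_dense,n_sparse entry counts per region.
#' @param seed RNG seed.
#' @param europe_prob probability that an entry is flagged as present in
#'   Europe.
#' @return data frame with `taxon`, `wbf_hz`, `mass_mg`, `in_europe`,
#'   `obs_prob`, ready for [load_reference_table()].
#' @export
synth_reference_table <- function(n_dense = 360L, n_less_dense = 14L,
                                  n_sparse = 33L, seed = 1L,
                                  europe_prob = 0.8) {
  with_seed(seed, {
    draw <- function(n, lo, hi, meanlog, sdlog) {
      if (n == 0) return(NULL)
      data.frame(wbf_hz = stats::runif(n, lo, hi),
                 mass_mg = stats::rlnorm(n, meanlog, sdlog))
    }
    parts <- rbind(
      draw(n_dense, 21, 240, log(15), 1.2),
      draw(n_less_dense, 240.001, 340, log(5), 0.8),
      draw(n_sparse, 340.001, 900, log(2), 0.6))
    if (n_sparse >= 1) {
      # pin one sparse entry at exactly 480 Hz (the canonical mosquito)
      i480 <- n_dense + n_less_dense + 1L
      parts$wbf_hz[i480] <- 480
    }
    n <- nrow(parts)
    data.frame(taxon = sprintf("taxon_%03d", seq_len(n)),
               wbf_hz = parts$wbf_hz, mass_mg = parts$mass_mg,
               in_europe = stats::runif(n) < europe_prob,
               obs_prob = 1)
  })
}
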