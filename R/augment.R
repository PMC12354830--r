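# Waveform-level training augmentation. All primitives are deterministic;
# augment_segment() draws from the caller's RNG stream and composes them
# with the training recipe's probabilities (50% augment at all, then 50%
# per technique).

#' Linear-interpolation resampling to a fixed length
#' @keywords internal
resample_linear <- function(x, n_out) {
  if (length(x) == n_out) return(x)
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out),
                rule = 2)$y
}

# Fit a waveform to exactly n samples: center-crop when longer, circular
# tiling when shorter (keeps signal statistics; zero-padding would inject
# silence the classifier could latch onto).
fit_length <- function(x, n) {
  m <- length(x)
  if (m == n) return(x)
  if (m > n) {
    start <- (m - n) %/% 2L
    return(x[(start + 1):(start + n)])
  }
  rep_len(x, n)
}

#' Phase-vocoder time stretching
#'
#' Classic STFT phase vocoder: magnitudes are linearly interpolated along
#' the frame axis and phases advanced by the measured inter-frame phase
#' increments, then overlap-added. `rate > 1` shortens the signal (plays
#' faster) without changing pitch.
#'
#' @param x numeric waveform.
#' @param rate stretch rate; output duration is approximately
#'   `length(x)/rate`.
#' @param n_fft,hop analysis FFT size and hop.
#' @return numeric waveform of length ~`length(x)/rate`.
#' @export
time_stretch <- function(x, rate, n_fft = 256L, hop = 64L) {
  stopifnot(rate > 0)
  if (abs(rate - 1) < 1e-12) return(x)
  n <- length(x)
  if (n < n_fft + hop) return(resample_linear(x, round(n / rate)))
  w <- hann_window(n_fft)
  n_frames <- 1L + (n - n_fft) %/% hop
  X <- vapply(seq_len(n_frames) - 1L, function(t) {
    stats::fft(x[(t * hop + 1):(t * hop + n_fft)] * w)
  }, complex(n_fft))
  mag <- Mod(X); ph <- Arg(X)
  steps <- seq(0, n_frames - 2L, by = rate)
  omega <- 2 * pi * hop * (0:(n_fft - 1L)) / n_fft
  phi <- ph[, 1L]
  out <- numeric(ceiling(length(steps)) * hop + n_fft)
  wsum <- numeric(length(out))
  pos <- 1L
  for (p in steps) {
    t0 <- floor(p); frac <- p - t0
    m <- (1 - frac) * mag[, t0 + 1L] + frac * mag[, t0 + 2L]
    frame <- Re(stats::fft(m * exp(1i * phi), inverse = TRUE)) / n_fft
    idx <- pos:(pos + n_fft - 1L)
    out[idx] <- out[idx] + frame * w
    wsum[idx] <- wsum[idx] + w^2
    dphi <- ph[, t0 + 2L] - ph[, t0 + 1L] - omega
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phi <- phi + omega + dphi
    pos <- pos + hop
  }
  good <- wsum > 1e-9
  out[good] <- out[good] / wsum[good]
  out[seq_len(pos - hop + n_fft - 1L)]
}

#' Pitch shifting by resampled time stretch
#'
#' Shifts all frequencies by `semitones` (factor `2^(semitones/12)`) while
#' preserving duration: the waveform is first time-stretched to compensate,
#' then resampled back to the original length.
#'
#' @param x numeric waveform.
#' @param semitones shift in semitones (+/-; the training recipe draws
#'   uniformly in \[-4, 4\]).
#' @return numeric waveform, same length as `x`.
#' @export
pitch_shift <- function(x, semitones) {
  if (abs(semitones) < 1e-12) return(x)
  r <- 2^(semitones / 12)
  y <- time_stretch(x, rate = 1 / r)
  resample_linear(y, length(x))
}

#' Circular time shift
#'
#' @param x numeric waveform.
#' @param frac shift as a fraction of the total length, in \[-0.5, 0.5\];
#'   positive shifts move content later (with wrap-around).
#' @return shifted waveform, same length.
#' @export
time_shift_circular <- function(x, frac) {
  n <- length(x)
  k <- round(frac * n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Stochastic training augmentation of a 1-second segment
#'
#' With probability `p_augment` the segment is augmented; if so, each
#' technique is applied independently with probability `p_each`:
#' pitch shift (+/- 4 semitones), time stretch (factor 0.8-1.25), circular
#' time shift (fraction -0.5 to +0.5), additive Gaussian noise (amplitude
#' 0.003 on the normalized scale) and mixing of a real noise segment from
#' `noise_bank`. Output is re-fit to exactly `length(x)` samples. Draws
#' from the current RNG stream; seed the session for reproducibility.
#'
#' @param x normalized waveform (length 4000 for the canonical pipeline).
#' @param noise_bank list of normalized noise waveforms (may be empty; the
#'   real-noise mix is then skipped with a warning when drawn).
#' @param p_augment probability of augmenting at all (default 0.5).
#' @param p_each probability of each technique given augmentation
#'   (default 0.5).
#' @return augmented waveform, same length as `x`.
#' @export
augment_segment <- function(x, noise_bank = list(),
                            p_augment = 0.5, p_each = 0.5) {
  n <- length(x)
  if (stats::runif(1) >= p_augment) return(x)
  if (stats::runif(1) < p_each) {
    x <- pitch_shift(x, stats::runif(1, -4, 4))
  }
  if (stats::runif(1) < p_each) {
    x <- fit_length(time_stretch(x, stats::runif(1, 0.8, 1.25)), n)
  }
  if (stats::runif(1) < p_each) {
    x <- time_shift_circular(x, stats::runif(1, -0.5, 0.5))
  }
  if (stats::runif(1) < p_each) {
    x <- x + stats::rnorm(n, 0, 0.003)
  }
  if (stats::runif(1) < p_each) {
    if (length(noise_bank) == 0) {
      warning("empty noise bank: real-noise mix skipped", call. = FALSE)
    } else {
      nb <- noise_bank[[sample.int(length(noise_bank), 1)]]
      x <- x + stats::runif(1, 0.2, 1) * fit_length(nb, n)
    }
  }
  fit_length(x, n)
}
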