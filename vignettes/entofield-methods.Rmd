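---
title: "entofield: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{entofield: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
assumes, which tunable parameters matter and why their defaults are what
they are, what the simulator does and does not emulate, and where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The measurement model

A flying insect charges triboelectrically and disturbs the local
atmospheric electric field. A differential electrostatic probe converts
this into a voltage whose dominant periodicity is the wing-beat frequency
(WBF) with a stack of harmonics; the usable band is roughly 5–2000 Hz and
recordings are one minute of 16-bit samples at 4 kHz. Everything
downstream treats the recording as an audio-like signal: the WBF plays the
role of a fundamental frequency, and biomass enters only through a
WBF-to-body-mass reference table.

Integer samples are normalized to [−1, 1) by division by 32768 before any
DSP; all amplitude parameters below (noise 0.003, simulator peak
amplitudes) live on that scale.

## Power-line interference

**Assumption.** Mains pickup is a stationary narrowband line at 50 or
60 Hz plus harmonics, present throughout the minute; insect tones near
50 Hz are transient.

**Detection.** The minute is split into 4 equal chunks. Per chunk, a Welch
PSD (1-s Hann windows, 50 % overlap, 1 Hz resolution — the minimum that
separates 50 Hz from its comparison bands) is compared between the target
band (candidate ±1 Hz) and the adjacent bands ([−5, −2] and [+2, +5] Hz
around the candidate). A chunk votes "mains" when the target mean PSD
exceeds 2× the adjacent mean; interference is confirmed only if **all**
chunks vote yes. The band widths and ×2 margin are declared package
choices (the source only states "greater than"); the margin keeps false
positives on white noise below 1 % while the all-chunks rule protects
insects hovering at exactly 50 Hz.

**Cancellation.** A cascade of RBJ second-order IIR notches at every
harmonic `k·f_mains` below Nyquist. The notch bandwidth is constant in Hz
(`f_mains/Q`, default Q = 30 at the fundamental, so the quality factor of
the k-th notch is k·Q). A constant-Q design was considered and rejected:
at the 39th harmonic of 50 Hz a Q = 30 notch is ~65 Hz wide and would
attenuate wing-beat ridges tens of Hz away, violating the pass-band goal
of < 1 dB at ≥ 5 Hz from every harmonic.

## Segmentation and spectrogram

Segments are exactly 1 s (4000 samples), non-overlapping, from t = 0;
a trailing partial second is discarded. The canonical spectrogram is
129 × 32: FFT length 256 (129 one-sided bins, 15.625 Hz each) and hop 128
with centered reflect-padded framing (1 + ⌊4000/128⌋ = 32 frames). This is
the only power-of-two parameter set consistent with that published shape;
the window is Hann. Raw magnitudes are stored; the detector applies
`log1p` compression and per-segment max normalization at consumption, a
standard dynamic-range choice for audio CNNs.

## The detector

Architecture: conv 3×3 ×16 → ReLU → batch norm → dropout → conv 3×3 ×32 →
ReLU → batch norm → max-pool 2×2 → flatten → dense 256 → batch norm →
ReLU → dropout → dense 1 (sigmoid). Kernel 3×3, pool 2×2, dropout 0.5,
Adam at 1e-3, batch 32, early stopping on validation loss (patience 5)
are conventional defaults, all exposed in `detector_config()`. The loss is
binary cross-entropy with the positive class weighted by the training
negative/positive count ratio; no resampling.

Augmentation is applied per epoch per segment with probability 0.5; given
augmentation, each technique fires independently with probability 0.5:
pitch shift ±4 semitones and time stretch 0.8–1.25 (phase vocoder on the
waveform, before the spectrogram), circular time shift ±0.5 of the length,
Gaussian noise of amplitude 0.003, and additive mixing of a real noise
segment. The time-shift boundary handling (circular vs zero-padded) was
unspecified in the source; circular keeps signal statistics stationary.
Both classes are augmented identically so augmentation artifacts carry no
label information.

The CNN is implemented from scratch (im2col + BLAS gemm, batch norm,
dropout, Adam) because no deep-learning framework is available in the
supported environment. Gradients were verified against central finite
differences for every parameter tensor. Checkpoints are JSON weight dumps.
A note on throughput: the training loop allocates ~100 MB im2col buffers
per batch, and glibc's default mmap threshold makes those allocations
page-fault-bound (two orders of magnitude slowdown); the package raises
the threshold at load time via a small C init hook.

## WBF estimation

Frame-level F0 uses a probabilistic YIN: the squared-difference function
(computed by FFT cross-correlation), its cumulative-mean-normalized form,
local minima refined by parabolic interpolation, a Beta(2, 18) prior over
absolute thresholds turning dip depths into candidate probabilities (the
first dip below a threshold wins, which favors the fundamental over
sub-harmonics), and Viterbi decoding over 48-per-octave log-spaced pitch
states plus an unvoiced state. Search range 20–2000 Hz: the floor is the
discard rule's minimum plausible WBF, the ceiling the sensor band edge.

Two parameters deserve justification:

* **Frame length 512 samples (128 ms), hop 256.** The stationarity
  assumption holds at this scale, and — decisive — the discard rule
  requires σ\_f0 ≥ 1 Hz for genuine insects. Wing-beat wobble lives on
  ~100 ms timescales; 0.5 s frames would average it away and make the rule
  discard true insects. (An earlier 2048-sample draft did exactly that.)
* **4× band-limited upsampling before the lag search.** At 480 Hz the
  period is ~8 samples; parabolic interpolation on the raw lag grid leaves
  ~5 Hz errors. Upsampling by 4 (zero-padded FFT) restores sub-Hz accuracy
  across the 50–500 Hz range at negligible cost.

**Discard rule.** A segment is discarded when μ\_f0 < 20 Hz (wind rumble),
**or** σ\_f0 < 1 Hz (machine-stable tones are not insects), **or**
σ\_f0/μ\_f0 > 0.8 (erratic tracks). The published sentence joins the three
with "and" and prints the ratio as "< 0.8", but its own rationales
describe three independent discard conditions and the exclusion of
*drastically changing* WBFs; the rationale-consistent reading is the
default and the literal one is available via `ratio_as_printed` and
`combine_and`.

## Event aggregation

Adjacent kept segments (consecutive indices only) are chained while the
pair passes `IoU([μ±σ/2]) ≥ 0.1` and Bhattacharyya similarity ≥ 0.7.
Two open points were resolved as follows:

* The published Eq. for "BC" is the Gaussian Bhattacharyya **distance**
  (0 for identical inputs), so thresholding it at ≥ 0.7 would merge
  dissimilar segments; the threshold is applied to the coefficient
  `exp(−D)` instead (`bc_as_printed` restores the literal reading).
* The published regrouped σ, `sqrt(Σ 1/σᵢ²)`, grows with the number of
  members and has units 1/Hz; the default is the inverse-variance standard
  error `sqrt(1/Σ 1/σᵢ²)` (`sigma_as_printed` restores the literal form).
  A property test documents that the corrected form never exceeds the
  smallest member σ while the printed one grows with n.
* Chaining compares each new segment against the **previous raw segment**,
  not the running regrouped event: regrouped σ shrinks as members
  accumulate, which would make long events progressively harder to extend
  for no physical reason.

Zero-width intervals (σ = 0 cannot survive the discard rule but can be
constructed) have IoU 1 if the means coincide, else 0.

## Biomass lookup

Masses are milligrams internally; period reports are grams. "Exact" match
on a continuous frequency axis means |μ − entry| < 0.01 Hz. The candidate
window grows by 0.5 Hz steps with an **open** boundary (an entry exactly on
the current half-width is picked up at the next step), capped at
`max(10, σ\_f0)/2` where σ is the event's regrouped value. Region
boundaries: dense ≤ 240 Hz, less dense (240, 340], sparse > 340 Hz.
Misses fall back to the **own region's** mass median for dense and less
dense (the source is ambiguous between "dense median" and "own median" for
the less dense region; the more local estimate was chosen, with
`fallback_dense_median` restoring the other reading), and to the mass of
the entry nearest 480 Hz — a mosquito — in the sparse region. With more
than one candidate, non-European entries are removed; zero survivors give
mass 0, several give an observation-probability-weighted mean (the
placeholder probability 1 makes this an arithmetic mean). Windows may
straddle region boundaries; the region is used only to pick fallbacks.

## Validation statistics

Spearman ρ with average-rank ties and the t-approximation p-value at
n = 26 (exact permutation available by flag); OLS slope with the standard
t-test; Fisher r-to-z for comparing two correlations,
`z = (atanh ρ₁ − atanh ρ₂)/√(1/(n₁−3) + 1/(n₂−3))`, two-tailed normal p.
The independent-samples z-variant reproduces the published worked examples
from the published ρ and n, so it is the one implemented; the dependence
between coefficients computed on the same trapping periods is knowingly
ignored, as in the source analysis. A Shapiro-Wilk check is provided but
purely advisory — the pipeline always reports Spearman.

## The simulator: what it emulates, what it does not

An insect pass is synthesized as a harmonic stack: fundamental at the
nominal WBF with 4 harmonics decaying geometrically (ratio 0.6, matching
the look of observed ridge stacks), a mean-reverting (Ornstein-Uhlenbeck)
jitter on the fundamental — stationary sd 3 Hz, correlation time 0.1 s —
and a Hann (approach-retreat) amplitude envelope. The jitter parameters
encode two biological/statistical constraints chosen a priori: insect WBFs
wobble by a few Hz on sub-second timescales (so within-segment σ\_f0
comfortably exceeds the 1 Hz discard floor), and second-to-second mean
drift stays within the merge tolerances for a single insect. Mains is a
deterministic 1/k harmonic stack; background is white Gaussian noise.
Ground truth records each event's *realized* time-averaged fundamental,
which is the reference for recovery checks (the nominal WBF differs from
it by the jitter's sample mean). Noise, mains phases and each event's
jitter are drawn from separate seed substreams, so toggling one component
— say, mains on vs off — leaves the other components' realizations
bit-identical; the mains-robustness test relies on exactly this.

Event durations in the end-to-end recovery test are 2–4 s, representative
of sustained passes in published example spectrograms, where activity
bursts span several seconds; sub-second flybys are exercised separately in
the dataset-curation tests (symmetric padding, rounding down).

Not emulated: electrostatic geometry of the dual probe (amplitude
envelopes stand in for spatial sensitivity, no blind-plane effects), no
frequency Doppler, no overlapping insects within a segment, no real-world
noise library (the "real noise" class mixes synthetic hum, wind rumble and
stable tones). A green end-to-end test therefore establishes that the
pipeline's stages compose correctly and recover known signals at
SNR ≥ 10 dB — not that the detector would match its published field
performance, which depended on 129 sensors of labeled field data that are
not available here.

## Numerical choices and degenerate inputs

* STFT of an all-zero segment is all-zero; max-normalization leaves it
  all-zero rather than dividing by zero.
* Probabilities are clamped to [1e-12, 1−1e-12] inside the cross-entropy.
* Batch-norm eval mode uses running statistics (momentum 0.9, eps 1e-5);
  dropout is a no-op at evaluation, so inference is deterministic.
* The decision threshold ties at exactly 0.5 to "insect" — arbitrary but
  fixed and documented.
* Welch detection requires ≥ 1 full 1-s window per chunk; shorter
  recordings raise an error rather than silently degrading resolution.
* All generators are pure functions of (spec, seed) and restore the
  caller's RNG state.

## Known limitations

* Event merging never crosses one-minute recording boundaries.
* One F0 track per segment: two simultaneous insects yield one event.
* No octave-error correction beyond the Viterbi prior; a harmonically weak
  fundamental can be tracked an octave high (tolerated in up to 5 % of
  cases by the recovery criterion).
* The biomass scale inherits every uncertainty of the reference table
  (dry/wet mass state, literature heterogeneity); the pipeline treats the
  table as given.
* The test-suite detector is trained on synthetic, cleanly separable data;
  its AUC says nothing about field performance.
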