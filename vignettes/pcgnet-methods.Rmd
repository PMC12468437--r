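---
title: "Models and methods behind pcgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pcgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pcgnet` is an end-to-end pipeline for two-class screening of infant
heart sounds: synthesize or load phonocardiogram (PCG) audio, turn it
into one-dimensional or two-dimensional time-frequency representations,
train one of three reference network architectures, and evaluate with
confusion-matrix metrics under cross-validated, balanced protocols. This
vignette explains the underlying models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic corpus does and
does not demonstrate.

## 1. The synthetic phonocardiogram model

A healthy PCG is dominated by two transients per cardiac cycle: S1
(atrioventricular valve closure) and S2 (semilunar valve closure). The
generator models each as a Gaussian-enveloped sinusoid
(`synth_transient()`): S1 at 50 Hz lasting 90 ms, S2 at 80 Hz lasting
70 ms with 0.8 × S1 amplitude, values chosen to mimic textbook PCG
morphology. Cycles are placed at interval $60/\mathrm{HR}$ seconds, so a
six-second recording carries $\lfloor 6\,\mathrm{HR}/60 \rfloor$ beats —
6 at 60 bpm, 10 at 100 bpm, the physiological range the corpus emulates.
S2 onset follows S1 by a fixed systolic fraction of the cycle (default
0.35). Optional Gaussian onset jitter (default 0 in unit tests, 5 ms in
the corpus preset) breaks perfect periodicity.

Abnormal recordings add a **systolic murmur**: white noise band-pass
filtered (4th-order Butterworth, zero-phase `filtfilt`) to a
condition-specific band, scaled to a condition-specific gain relative to
S1, Hann-windowed, and inserted over the central portion of the
S1-offset-to-S2-onset interval. Six presets (VSD, ASD, PDA, TOF, PS, AS)
differ in band (e.g. 150–400 Hz for VSD, 200–500 Hz for PS), gain
(0.35–0.5) and systolic coverage (0.6–0.95); they are stylized
caricatures — holosystolic vs. ejection timing, higher bands for
stenoses — not hemodynamic simulations. A `normal` pseudo-preset has
gain 0, so the two classes differ *only* in the murmur term; the
`murmur_gain` override produces exact null corpora for leakage tests.

Sampling rate defaults to 4000 Hz: heart-sound energy lies below
~1 kHz, leaving a comfortable Nyquist margin. Output is peak-normalized
to 0.9 and quantized to 16-bit PCM WAV. The study-emulation preset
writes 60 six-second recordings, 30 normal and 30 abnormal cycling
round-robin through the six presets, with heart rates drawn uniformly
from 60–100 bpm. One master seed derives per-recording seeds by
counter, so corpora are bit-reproducible.

**What the simulator does not model:** diastolic murmurs, respiration
and ambient noise, sensor transfer functions, inter-patient variability
in S1/S2 morphology. Tests passing on this corpus show the pipeline
recovers a localized band-energy cue under timing variability; they do
not certify performance on clinical recordings.

## 2. Feature extraction

All extractors share the framing convention
$n_\text{frames} = 1 + \lfloor (N - L)/h \rfloor$ with Hann-windowed
frames of $L$ samples and hop $h$ (defaults 25 ms / 10 ms, community
defaults for biomedical audio). Logs are floored at `log_floor`
(default 1e-10), so silence never produces `-Inf` and all outputs are
finite by construction.

* **MFCC** (the 1D representation): one-sided power spectrum → 26
  triangular mel filters (HTK mel scale, 0 Hz–Nyquist) → `log` →
  orthonormal DCT-II, keeping 13 coefficients. Frames are timesteps for
  the recurrent model.
* **STFT spectrogram**: magnitude of the framed FFT (`n_fft` defaults
  to the next power of two at or above the frame length).
* **Morlet scalogram**: FFT-based continuous wavelet transform with the
  analytic Morlet mother wavelet (shape parameter 6); scales log-spaced
  so center frequencies cover 20 Hz–Nyquist; magnitudes sampled every
  hop so the time axis matches the other extractors.

`to_image()` renders any of these matrices as an $H \times W \times 3$
image in $[0,1]$: log-compress (magnitude extractors only — MFCCs are
already cepstral/log-domain and may be negative), bilinear-resize, then
min–max normalize, replicating the result onto three identical channels
(no colormap, keeping the rendering deterministic and
library-independent). Normalization is applied *after* the resize so
every non-constant image spans exactly $[0,1]$; a constant matrix maps
to all zeros by convention.

## 3. The three architectures

Specifications are pure data (`model_spec`): an ordered layer list plus
a training configuration, supporting shape inference and closed-form
parameter counting before any weight exists.

* **model1** — MFCC sequence → LSTM(128) → dropout 0.2 → LSTM(128) →
  dropout 0.2 → LSTM(128) → dropout 0.2 → dense head → softmax(2);
  50 epochs, batch 32. The width of the dense head before the softmax
  is open in the source description; the default is 64 ReLU units,
  configurable.
* **model2** — 128×128×3 image → [conv 3×3/stride 1 → max-pool 2×2/
  stride 2 → batch norm] × 3 with 32/64/128 filters → flatten →
  dense(128, ReLU) → dropout 0.5 → softmax(2); 100 epochs, batch 32.
  Batch norm is placed after pooling, honoring the source description
  literally. Convolutions use valid padding (no padding); padding is
  exposed nowhere else because no padding choice reproduces the
  published parameter counts (below).
* **model3** — 64×64×3 image → two conv blocks (32 then 64 filters) →
  the final $H' \times W' \times C$ feature map is read as a sequence of
  $H'$ timesteps with $W' \cdot C$ features (rows as time, preserving
  the image's ordering along its first axis) → LSTM(64, sequences) →
  LSTM(128) → dropout 0.2 → dense head → softmax(2); 50 epochs by
  default, 100 as the documented alternative.

An optional late-fusion wrapper (`fuse_probabilities()`) averages the
class probabilities of independently trained models, the simplest
reading of combining the 1D and 2D streams; the single-stream hybrid is
the primary model3.

### Parameter counting

`count_parameters()` uses the standard closed forms — dense
$(d_{in}+1)\,d_{out}$, convolution $(k_h k_w c_{in} + 1) f$, LSTM
$4(u(d_{in}+u)+u)$, batch norm $2c$ — and is verified in the test suite
against enumeration of the actually materialized weight arrays. The
resulting totals are 344,258 (model1, 598×13 input), 3,305,346
(model2) and 372,802 (model3). Published counts for these
architectures (331,010 / 9,914,309 / 3,346,370) could not be reproduced
under any standard padding/head convention; the builders therefore
report their true counts. The qualitative cost ordering —
1D LSTM lightest, hybrid an order of magnitude lighter than the pure
image CNN — is preserved.

## 4. The training engine

With no deep-learning framework available to R, the engine is written
in base-R matrix algebra: convolutions by patch extraction (im2col) and
one matrix product; max-pool by offset comparison with argmax caching;
batch normalization with batch statistics in training and running
moments (momentum 0.9, $\varepsilon=10^{-5}$) at inference; LSTM with
input/forget/cell/output gates, forget bias initialized at 1, and full
backpropagation through time; inverted dropout; Glorot-uniform
initialization; Adam ($\beta_1=0.9$, $\beta_2=0.999$,
$\varepsilon=10^{-8}$, learning rate $10^{-3}$ — unstated in the source
description, so the Adam default) on the categorical cross-entropy.
Analytic gradients of every layer kind are validated against central
finite differences in the test suite (relative error ~1e-6).

Numerical choices worth knowing:

* Softmax is computed with the row-max subtracted; the loss gradient
  enters the output layer as $(p - y)/B$ directly.
* Epoch-end history losses are evaluated in **inference mode** over the
  full training set, so dropout noise never enters the recorded
  trajectory and a zero learning rate yields a constant trajectory.
  Batch-norm running moments are model *state*, not trained weights:
  they continue to update during training passes even at learning rate
  zero, exactly as mainstream frameworks behave.
* Ties in `predict_label()` go to the first class, `abnormal` —
  conservative for a screening tool.
* Training is fully reproducible from `train_config$seed`
  (initialization, shuffling, dropout masks, validation holdout).

## 5. Evaluation protocols

The positive class is `abnormal` (the patient class). From the
confusion matrix, `compute_metrics()` returns Acc, Se, Sp and the
modified accuracy $\mathrm{MAcc} = (\mathrm{Sp}+\mathrm{Se})/2$, plus
per-class precision/recall/F1 keyed `Ab`/`N`. Zero-denominator metrics
(e.g. sensitivity in a fold with no positives) return `NA` — an
explicit undefined marker, never silent NaN — and protocol averages
exclude them while reporting how many folds were affected.

* **Stratified split**: per-class largest-remainder rounding of the
  8:1:1 ratios (remainder ties broken in partition order: train,
  validation, test), then seeded shuffling. On the 60-recording corpus
  this forces 48/6/6 with both classes balanced everywhere.
* **Stratified k-fold** (default $k=10$): within each class, shuffled
  records are dealt round-robin, so fold sizes differ by at most one
  per class and every example is tested exactly once. Per-fold training
  derives its own seed from the master seed.
* **Repeated balanced protocol**: each iteration draws `n_per_class`
  records per class without replacement (defaults 218 + 218 — the
  resampling pool is interpreted as segment-level data, since the
  six-second windowing of longer recordings is how a 60-recording
  corpus can support such draws; `replace = TRUE` is available for
  small pools), runs the k-fold evaluation, and the report aggregates
  mean ± sd over the 50 iterations.
* **Extractor comparison**: identical split, identical model head and
  identical training seed across extractors, so the comparison is
  paired and differences are attributable to the extractor alone.

## 6. Problem sizes used in the shipped tests

The test suite and the worked examples run on deliberately small
problems chosen as the smallest sizes at which each property is
informative: the 60-recording study-emulation corpus for structural
checks; 20–24-recording high-SNR corpora (murmur gain 1.0, background
noise sd 0.005, fixed 80 bpm) for learner sanity checks — a
nearest-centroid oracle separates that fixture perfectly, so a learner
failing it is at fault, not the data; 15 training epochs for the hybrid
model, which reaches training accuracy 1.0 on the clean corpus by epoch
5; and 2–6 protocol iterations in bookkeeping tests. Null-corpus tests
(murmur gain 0) verify that cross-validated accuracy stays at chance,
i.e. the pipeline leaks no label information.

## 7. Known limitations

* The engine is CPU-only and unoptimized beyond BLAS-backed matrix
  products; training model2 at its full 128×128 input for 100 epochs on
  a large corpus is slow in plain R.
* The simulator's murmurs are stationary band-noise bursts; real
  murmurs have pitch contours, clicks and radiation patterns it does
  not attempt.
* Segmentation discards incomplete tails rather than padding; on
  corpora of exactly window-length recordings this is a no-op.
* The resampling pool for the full 218 + 218 protocol must come from
  windowed segments (or `replace = TRUE`); the package does not decide
  this for you.
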