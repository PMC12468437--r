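# pcgnet

Deep-learning screening of infant heart sounds (phonocardiograms, PCG) for
congenital heart defects, in pure R.

About 1% of newborns have a congenital heart defect (VSD, ASD, PDA, TOF,
pulmonary or aortic stenosis, ...). Many of these produce a **systolic
murmur** — band-limited turbulence noise between the two fundamental heart
sounds S1 and S2 — that a stethoscope picks up long before ECG or
echocardiography are ordered. `pcgnet` is a toolkit for building and
evaluating normal/abnormal classifiers on six-second stethoscope
recordings. It targets researchers who want a fully reproducible,
dependency-light reference pipeline: every stage, including network
training, runs in R with no deep-learning framework.

The package provides:

* **A synthetic PCG generator** — Gaussian-enveloped S1/S2 bursts per
  cardiac cycle at 60–100 bpm (so a 6 s recording carries 6–10 beats),
  with per-condition systolic murmur presets (band-passed, Hann-windowed
  noise). The study-emulation preset writes a 60-recording corpus
  (30 normal / 30 abnormal) as 16-bit PCM WAV plus a CSV manifest.
* **Feature extraction** — MFCC sequences (frames × coefficients) as the
  1D representation, and STFT spectrograms, Morlet scalograms or MFCC
  matrices rendered as fixed-size H×W×3 images in [0,1] as 2D
  representations.
* **Three reference architectures** as abstract layer specs with
  closed-form parameter counting and a matrix-based training engine
  (Adam, categorical cross-entropy, backpropagation through time):
  * `model1` — stacked LSTM (3 × 128 units, dropout 0.2) on MFCC
    sequences;
  * `model2` — 2D CNN (conv 32/64/128, 3×3, each with 2×2 max-pool and
    batch norm; dense 128; dropout 0.5) on 128×128×3 images;
  * `model3` — hybrid CNN→LSTM (conv 32/64 on 64×64×3 images, feature
    map read row-wise as a sequence into LSTM 64→128).
* **Evaluation** — confusion-matrix metrics with the patient class
  (`abnormal`) positive:

  Acc = (TP+TN)/(TP+FP+TN+FN), Se = TP/(TP+FN), Sp = TN/(FP+TN),
  **MAcc = (Sp+Se)/2**,

  per-class precision/F1, stratified 8:1:1 splits, stratified 10-fold
  cross-validation, a repeated balanced-resampling protocol (draws of
  218 + 218 signals, 50 iterations by default), paired extractor
  comparison, and training-cost reports.

## Worked example

```r
library(pcgnet)

## study-emulation corpus: 60 six-second recordings, 30 per class
manifest <- generate_dataset(synth_dataset_config(seed = 424242), "corpus")
class_counts(manifest)
#>   normal abnormal
#>       30       30

## stratified 8:1:1 split
split <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 1)
table(split$partition)
#>       test      train validation
#>          6         48          6

## 2D features and the hybrid model
data <- featurize_manifest(split, feature_config("stft", image_size = c(64, 64)),
                           mode = "image")
spec <- build_model3(config = train_config(epochs = 15, batch_size = 16, seed = 42))
tr <- split$partition == "train"
fit <- train_model(spec, data$x[tr, , , , drop = FALSE], data$y[tr])
tail(fit$history, 1)
#>    epoch   train_loss train_acc val_loss val_acc
#> 15    15 0.0001395472         1       NA      NA

## held-out metrics
te <- split$partition == "test"
pred <- predict_label(fit, data$x[te, , , , drop = FALSE])
compute_metrics(confusion(data$y[te], pred))
#> Acc 1.0000  Se 1.0000  Sp 1.0000  MAcc 1.0000  (n=6)

## training-cost comparison
cost_report(list(build_model1(c(598, 13)), build_model2(), build_model3()))
#>    model parameters epochs batch_size train_time_s
#> 2 model2    3305346    100         32           NA
#> 3 model3     372802     50         32           NA
#> 1 model1     344258     50         32           NA
```

On this clean synthetic corpus the hybrid network separates the classes
perfectly; the cost table shows the characteristic ordering — the 1D LSTM
is the lightest, the hybrid roughly an order of magnitude lighter than
the pure image CNN.

The same pipeline is scriptable through the installed CLI
(`exec/pcgnet`): `synth`, `split`, `featurize`, `train`, `evaluate`,
`compare`, `cost`, all driven by one `--seed`.

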