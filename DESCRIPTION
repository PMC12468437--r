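Package: pcgnet
Title: Deep Learning Classification of Infant Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for screening infant heart sounds for
    congenital heart defects. Synthesizes phonocardiogram-like audio with
    configurable systolic murmurs, extracts one-dimensional (MFCC sequence)
    and two-dimensional (STFT spectrogram, Morlet scalogram, MFCC image)
    time-frequency representations, trains three reference architectures
    (a stacked LSTM, a 2D convolutional network, and a hybrid
    convolution-to-LSTM network) with a self-contained matrix-based
    backpropagation engine, and evaluates them with confusion-matrix
    metrics (accuracy, sensitivity, specificity, modified accuracy),
    stratified k-fold cross-validation, and a balanced resampling
    protocol. Includes closed-form trainable-parameter counting for
    training-cost reports and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
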