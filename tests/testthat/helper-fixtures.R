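# Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Study-emulation corpus: 30 normal + 30 abnormal six-second recordings.
study_corpus <- function() {
  memo("study_corpus", function() {
    dir <- file.path(tempdir(), "pcgnet-study-corpus")
    generate_dataset(synth_dataset_config(seed = 424242L), dir)
  })
}

# Small labelled image set from high-SNR recordings (fast to featurize).
# The defaults (loud murmur, quiet background) give classes that a
# nearest-centroid oracle separates perfectly, so learners are tested on
# recoverable signal; murmur_gain = 0 produces a null corpus instead.
toy_images <- function(n_per_class = 8, size = 16, noise_sd = 0.005,
                       murmur_gain = 1.0, seed = 5L, extractor = "stft") {
  key <- paste("toy_images", n_per_class, size, noise_sd, murmur_gain,
               seed, extractor, sep = "_")
  memo(key, function() {
    cfg <- feature_config(extractor, image_size = c(size, size))
    x <- array(0, c(2 * n_per_class, size, size, 3))
    y <- character(2 * n_per_class)
    conds <- rep(c("VSD", "normal"), each = n_per_class)
    # fixed heart rate for every recording: the murmur is the only
    # systematic class difference, so a small dense probe suffices
    # (heart-rate variability is exercised by the convolutional tests)
    for (i in seq_along(conds)) {
      rec <- synthesize_recording(conds[i], heart_rate = 80,
                                  duration = 6, sample_rate = 4000,
                                  noise_sd = noise_sd,
                                  seed = derive_seed(seed, i),
                                  murmur_gain = if (conds[i] == "VSD") murmur_gain else 0)
      x[i, , , ] <- image_features(rec, cfg)
    }
    # under the null (murmur_gain = 0) both conditions sound identical but
    # the nominal class assignment is kept, to probe for leakage
    y <- rep(c("abnormal", "normal"), each = n_per_class)
    list(x = x, y = y)
  })
}

# A minimal trainable head used where the protocol, not the architecture,
# is under test.
toy_dense_builder <- function(epochs = 5, seed = 7L) {
  function(input_shape) {
    model_spec("toy", input_shape, list(
      layer_flatten(),
      layer_dense(8, "relu"),
      layer_dense(2, "softmax")
    ), train_config(epochs = epochs, batch_size = 8, learning_rate = 0.01,
                    seed = seed))
  }
}

# Small convolutional probe: generalizes far better than a dense probe on
# tiny image corpora, at negligible cost.
toy_conv_builder <- function(epochs = 20, seed = 7L) {
  function(input_shape) {
    model_spec("toyconv", input_shape, list(
      layer_conv2d(4), layer_maxpool2d(), layer_flatten(),
      layer_dense(8, "relu"),
      layer_dense(2, "softmax")
    ), train_config(epochs = epochs, batch_size = 8, learning_rate = 0.01,
                    seed = seed))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent parameter-count oracle: materialize the weights and count
# array elements, bypassing the closed-form arithmetic.
enumerate_parameters <- function(spec) {
  model <- init_model(spec, seed = 1L)
  sum(vapply(model$params, function(p) {
    if (is.null(p)) return(0)
    sum(vapply(p, length, numeric(1)))
  }, numeric(1)))
}
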