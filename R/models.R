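# Abstract model specifications.
#
# A model is an ordered list of layer descriptors plus a training
# configuration.  Specs are pure data: they support shape inference and
# closed-form trainable-parameter counting without instantiating weights,
# and the training engine (nn.R) materializes them.

#' Layer descriptors
#'
#' Constructors for the abstract layer types understood by the shape
#' inference, parameter counting, and training engine: 2D convolution
#' (valid padding), max pooling, batch normalization, flatten,
#' flatten-to-sequence (rows of the feature map become timesteps), LSTM,
#' dropout, and dense (with `"relu"`, `"linear"` or `"softmax"`
#' activation).
#'
#' @param filters,kernel,stride convolution filters, kernel `(kh, kw)`,
#'   and stride `(sh, sw)`.
#' @param pool pooling window `(ph, pw)`.
#' @param units LSTM/dense output width.
#' @param return_sequences LSTM returns the full hidden sequence rather
#'   than the last state.
#' @param rate dropout rate in `[0, 1)`.
#' @param activation dense activation.
#' @return a list of class `layer_spec`.
#' @name layer_spec
NULL

layer <- function(kind, ...) structure(list(kind = kind, ...), class = "layer_spec")

#' @rdname layer_spec
#' @export
layer_conv2d <- function(filters, kernel = c(3, 3), stride = c(1, 1)) {
  check_positive(filters, "filters")
  layer("conv2d", filters = as.integer(filters), kernel = as.integer(kernel),
        stride = as.integer(stride), activation = "relu")
}

#' @rdname layer_spec
#' @export
layer_maxpool2d <- function(pool = c(2, 2), stride = c(2, 2)) {
  layer("maxpool2d", pool = as.integer(pool), stride = as.integer(stride))
}

#' @rdname layer_spec
#' @export
layer_batchnorm <- function() layer("batchnorm")

#' @rdname layer_spec
#' @export
layer_flatten <- function() layer("flatten")

#' @rdname layer_spec
#' @export
layer_flatten_seq <- function() layer("flatten_seq")

#' @rdname layer_spec
#' @export
layer_lstm <- function(units, return_sequences = FALSE) {
  check_positive(units, "units")
  layer("lstm", units = as.integer(units), return_sequences = return_sequences)
}

#' @rdname layer_spec
#' @export
layer_dropout <- function(rate) {
  if (rate < 0 || rate >= 1)
    stop_pcg("dropout rate must lie in [0, 1)", class = "pcgnet_invalid_parameter")
  layer("dropout", rate = rate)
}

#' @rdname layer_spec
#' @export
layer_dense <- function(units, activation = c("relu", "linear", "softmax")) {
  check_positive(units, "units")
  layer("dense", units = as.integer(units), activation = match.arg(activation))
}

#' Training configuration
#'
#' Adam optimization of the categorical cross-entropy loss, matching the
#' training regime shared by all three architectures.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @param validation_split fraction of the training set held out for the
#'   per-epoch validation loss (0 disables).
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 32, learning_rate = 1e-3,
                         seed = 1L, validation_split = 0) {
  check_positive(epochs, "epochs")
  check_positive(batch_size, "batch_size")
  structure(list(optimizer = "adam", loss = "categorical_crossentropy",
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 validation_split = validation_split),
            class = "train_config")
}

#' Assemble a model specification
#'
#' @param name model name.
#' @param input_shape input shape excluding the batch axis:
#'   `(timesteps, features)` for sequence models, `(H, W, C)` for image
#'   models.
#' @param layers ordered list of [layer_spec] descriptors; the final layer
#'   must be a 2-unit softmax dense layer.
#' @param config a [train_config()].
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(name, input_shape, layers, config = train_config()) {
  last <- layers[[length(layers)]]
  if (last$kind != "dense" || last$activation != "softmax" || last$units != 2L)
    stop_pcg("final layer must be a softmax dense layer with 2 units",
             class = "pcgnet_invalid_parameter")
  spec <- structure(list(name = name, input_shape = as.integer(input_shape),
                         layers = layers, n_classes = 2L, config = config),
                    class = "model_spec")
  infer_shapes(spec)  # fail fast on unresolvable shape chains
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  shapes <- infer_shapes(x)
  cat(sprintf("<model_spec> %s  input (%s)  %s parameters\n", x$name,
              paste(x$input_shape, collapse = "x"),
              format(count_parameters(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    detail <- switch(l$kind,
      conv2d = sprintf("filters=%d kernel=%s", l$filters, paste(l$kernel, collapse = "x")),
      maxpool2d = sprintf("pool=%s", paste(l$pool, collapse = "x")),
      lstm = sprintf("units=%d%s", l$units, if (l$return_sequences) " (sequences)" else ""),
      dropout = sprintf("rate=%g", l$rate),
      dense = sprintf("units=%d %s", l$units, l$activation),
      "")
    cat(sprintf("  %-12s %-28s -> (%s)\n", l$kind, detail,
                paste(shapes[[i + 1]], collapse = "x")))
  }
  invisible(x)
}

conv_out <- function(n, k, s) (n - k) %/% s + 1L

# Shapes before layer 1, after layer 1, ..., after last layer.
infer_shapes <- function(spec) {
  shapes <- vector("list", length(spec$layers) + 1L)
  shapes[[1]] <- spec$input_shape
  s <- spec$input_shape
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    s <- switch(l$kind,
      conv2d = {
        if (length(s) != 3) stop_pcg("layer %d (conv2d) needs a (H, W, C) input, got (%s)",
                                     i, paste(s, collapse = ","), class = "pcgnet_shape_error")
        if (s[1] < l$kernel[1] || s[2] < l$kernel[2])
          stop_pcg("layer %d (conv2d) kernel larger than input", i, class = "pcgnet_shape_error")
        c(conv_out(s[1], l$kernel[1], l$stride[1]),
          conv_out(s[2], l$kernel[2], l$stride[2]), l$filters)
      },
      maxpool2d = {
        if (length(s) != 3) stop_pcg("layer %d (maxpool2d) needs a (H, W, C) input",
                                     i, class = "pcgnet_shape_error")
        c(conv_out(s[1], l$pool[1], l$stride[1]),
          conv_out(s[2], l$pool[2], l$stride[2]), s[3])
      },
      batchnorm = s,
      flatten = prod(s),
      flatten_seq = {
        if (length(s) != 3) stop_pcg("layer %d (flatten_seq) needs a (H, W, C) input",
                                     i, class = "pcgnet_shape_error")
        c(s[1], s[2] * s[3])
      },
      lstm = {
        if (length(s) != 2) stop_pcg("layer %d (lstm) needs a (timesteps, features) input",
                                     i, class = "pcgnet_shape_error")
        if (l$return_sequences) c(s[1], l$units) else l$units
      },
      dropout = s,
      dense = {
        if (length(s) != 1) stop_pcg("layer %d (dense) needs a flat input, got (%s)",
                                     i, paste(s, collapse = ","), class = "pcgnet_shape_error")
        l$units
      },
      stop_pcg("unknown layer kind '%s'", l$kind, class = "pcgnet_shape_error"))
    shapes[[i + 1]] <- as.integer(s)
  }
  shapes
}

#' Count trainable parameters in closed form
#'
#' Uses the standard per-layer formulas: dense `(in + 1) * out`;
#' convolution `(kh * kw * c_in + 1) * filters`; LSTM
#' `4 * (units * (in + units) + units)` (four gates, each with input and
#' recurrent weights plus bias); batch normalization `2 * channels`
#' (scale and shift; running moments are not trainable).
#'
#' @param spec a [model_spec()].
#' @return total trainable parameter count (integer-valued double).
#' @export
count_parameters <- function(spec) {
  shapes <- infer_shapes(spec)
  total <- 0
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    s_in <- shapes[[i]]
    total <- total + switch(l$kind,
      conv2d = (prod(l$kernel) * s_in[3] + 1) * l$filters,
      lstm = 4 * (l$units * (s_in[2] + l$units) + l$units),
      dense = (s_in[1] + 1) * l$units,
      batchnorm = 2 * s_in[length(s_in)],
      0)
  }
  total
}

#' Model 1: stacked LSTM for 1D sequence representations
#'
#' Three 128-unit LSTM layers, each followed by dropout 0.2, then a dense
#' head and a 2-unit softmax output.  Trained for 50 epochs with batch
#' size 32 by default.
#'
#' @param input_shape `(timesteps, features)` of the MFCC sequence input.
#' @param head_units width of the dense layer before the softmax output.
#' @param config optional [train_config()] override.
#' @return a [model_spec()].
#' @export
build_model1 <- function(input_shape, head_units = 64,
                         config = train_config(epochs = 50, batch_size = 32)) {
  if (length(input_shape) != 2 || any(input_shape < 1))
    stop_pcg("input_shape must be (timesteps, features), both >= 1",
             class = "pcgnet_invalid_parameter")
  model_spec("model1", input_shape, list(
    layer_lstm(128, return_sequences = TRUE),
    layer_dropout(0.2),
    layer_lstm(128, return_sequences = TRUE),
    layer_dropout(0.2),
    layer_lstm(128),
    layer_dropout(0.2),
    layer_dense(head_units, "relu"),
    layer_dense(2, "softmax")
  ), config)
}

#' Model 2: 2D CNN for image representations
#'
#' Three convolution blocks (32, 64, 128 filters; 3x3 kernels, stride 1;
#' each followed by 2x2/stride-2 max pooling and batch normalization),
#' then flatten, a 128-unit ReLU dense layer, dropout 0.5, and a 2-unit
#' softmax.  Expects 128x128x3 images; trained for 100 epochs with batch
#' size 32 by default.
#'
#' @param input_shape image shape `(H, W, 3)`.
#' @param config optional [train_config()] override.
#' @return a [model_spec()].
#' @export
build_model2 <- function(input_shape = c(128, 128, 3),
                         config = train_config(epochs = 100, batch_size = 32)) {
  model_spec("model2", input_shape, list(
    layer_conv2d(32), layer_maxpool2d(), layer_batchnorm(),
    layer_conv2d(64), layer_maxpool2d(), layer_batchnorm(),
    layer_conv2d(128), layer_maxpool2d(), layer_batchnorm(),
    layer_flatten(),
    layer_dense(128, "relu"),
    layer_dropout(0.5),
    layer_dense(2, "softmax")
  ), config)
}

#' Model 3: hybrid CNN-to-LSTM network
#'
#' Two convolution blocks (32 then 64 filters, 3x3, each with 2x2 max
#' pooling and batch normalization) on 64x64x3 images; the final feature
#' map is read as a sequence (rows as timesteps, columns x channels as
#' features) into two LSTM layers of 64 and 128 units, followed by
#' dropout 0.2, a dense head, and a 2-unit softmax.  Trained for 50
#' epochs (batch 32) by default; 100 epochs is the documented alternative.
#'
#' @param input_shape image shape, `(64, 64, 3)` by default.
#' @param head_units width of the dense layer before the softmax output.
#' @param config optional [train_config()] override.
#' @return a [model_spec()].
#' @export
build_model3 <- function(input_shape = c(64, 64, 3), head_units = 64,
                         config = train_config(epochs = 50, batch_size = 32)) {
  model_spec("model3", input_shape, list(
    layer_conv2d(32), layer_maxpool2d(), layer_batchnorm(),
    layer_conv2d(64), layer_maxpool2d(), layer_batchnorm(),
    layer_flatten_seq(),
    layer_lstm(64, return_sequences = TRUE),
    layer_lstm(128),
    layer_dropout(0.2),
    layer_dense(head_units, "relu"),
    layer_dense(2, "softmax")
  ), config)
}
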