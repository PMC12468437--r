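# Matrix-based training engine.
#
# Materializes a model_spec into weight matrices, and implements forward,
# backpropagation (including backpropagation through time for LSTM
# layers) and Adam updates with base-R matrix operations.  Convolutions
# are computed by patch extraction (im2col) followed by one matrix
# product, the standard dense-algebra formulation.
#
# Array conventions: batches are the first axis.  Image tensors are
# (B, H, W, C), sequences (B, T, D), flat features (B, D).
# Convolution weights are (kh*kw*C_in) x F with patch rows ordered kernel
# row fastest, then kernel column, then channel; LSTM gate blocks are
# ordered input, forget, cell, output.

# ---- patch extraction -------------------------------------------------

im2col <- function(x, kh, kw, sh, sw) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  OH <- (H - kh) %/% sh + 1L
  OW <- (W - kw) %/% sw + 1L
  P <- matrix(0, B * OH * OW, kh * kw * C)
  col <- 0L
  for (c in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    col <- col + 1L
    P[, col] <- x[, seq(i, by = sh, length.out = OH),
                    seq(j, by = sw, length.out = OW), c]
  }
  P
}

col2im <- function(dP, in_dim, kh, kw, sh, sw) {
  B <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]; C <- in_dim[4]
  OH <- (H - kh) %/% sh + 1L
  OW <- (W - kw) %/% sw + 1L
  dx <- array(0, in_dim)
  col <- 0L
  for (c in seq_len(C)) for (j in seq_len(kw)) for (i in seq_len(kh)) {
    col <- col + 1L
    ri <- seq(i, by = sh, length.out = OH)
    ci <- seq(j, by = sw, length.out = OW)
    dx[, ri, ci, c] <- dx[, ri, ci, c] + array(dP[, col], c(B, OH, OW))
  }
  dx
}

# ---- initialization ---------------------------------------------------

glorot <- function(n_in, n_out, dims = c(n_in, n_out)) {
  limit <- sqrt(6 / (n_in + n_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

init_layer <- function(l, s_in) {
  switch(l$kind,
    conv2d = {
      fan_in <- prod(l$kernel) * s_in[3]
      list(W = glorot(fan_in, l$filters), b = numeric(l$filters))
    },
    dense = list(W = glorot(s_in[1], l$units), b = numeric(l$units)),
    lstm = {
      D <- s_in[2]; H <- l$units
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1  # forget-gate bias at 1 eases early training
      list(Wx = glorot(D, 4 * H), Wh = glorot(H, 4 * H), b = b)
    },
    batchnorm = {
      C <- s_in[length(s_in)]
      list(gamma = rep(1, C), beta = numeric(C))
    },
    NULL)
}

#' Materialize a model specification into an untrained model
#'
#' @param spec a [model_spec()].
#' @param seed seed for weight initialization (Glorot uniform).
#' @return an object of class `pcg_model`.
#' @export
init_model <- function(spec, seed = spec$config$seed) {
  shapes <- infer_shapes(spec)
  params <- with_seed(seed, lapply(seq_along(spec$layers), function(i)
    init_layer(spec$layers[[i]], shapes[[i]])))
  state <- lapply(spec$layers, function(l) {
    if (l$kind == "batchnorm") list(mean = NULL, var = NULL) else NULL
  })
  structure(list(spec = spec, params = params, state = state,
                 classes = c("abnormal", "normal"), history = NULL),
            class = "pcg_model")
}

# ---- forward ----------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

forward_model <- function(model, x, training = FALSE) {
  spec <- model$spec
  state <- model$state
  caches <- vector("list", length(spec$layers))
  a <- x
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    p <- model$params[[i]]
    res <- switch(l$kind,
      conv2d = {
        d <- dim(a)
        P <- im2col(a, l$kernel[1], l$kernel[2], l$stride[1], l$stride[2])
        Z <- P %*% p$W
        Z <- Z + rep(p$b, each = nrow(Z))
        A <- Z * (Z > 0)
        OH <- (d[2] - l$kernel[1]) %/% l$stride[1] + 1L
        OW <- (d[3] - l$kernel[2]) %/% l$stride[2] + 1L
        list(out = array(A, c(d[1], OH, OW, l$filters)),
             cache = list(P = P, Z = Z, in_dim = d))
      },
      maxpool2d = forward_maxpool(a, l),
      batchnorm = forward_batchnorm(a, p, state[[i]], training),
      flatten = {
        d <- dim(a)
        list(out = matrix(a, d[1], prod(d[-1])), cache = list(in_dim = d))
      },
      flatten_seq = {
        d <- dim(a)
        list(out = array(a, c(d[1], d[2], d[3] * d[4])), cache = list(in_dim = d))
      },
      lstm = forward_lstm(a, p, l$return_sequences),
      dropout = {
        if (training && l$rate > 0) {
          mask <- array((stats::runif(length(a)) >= l$rate) / (1 - l$rate),
                        dim(a) %||% length(a))
          list(out = a * mask, cache = list(mask = mask))
        } else list(out = a, cache = list(mask = NULL))
      },
      dense = {
        Z <- a %*% p$W
        Z <- Z + rep(p$b, each = nrow(Z))
        A <- switch(l$activation,
          relu = Z * (Z > 0),
          linear = Z,
          softmax = {
            e <- exp(Z - apply(Z, 1, max))
            e / rowSums(e)
          })
        list(out = A, cache = list(a_in = a, Z = Z))
      })
    if (l$kind == "batchnorm" && training) state[[i]] <- res$state
    caches[[i]] <- res$cache
    a <- res$out
  }
  list(out = a, caches = caches, state = state)
}

forward_maxpool <- function(a, l) {
  d <- dim(a)
  ph <- l$pool[1]; pw <- l$pool[2]; sh <- l$stride[1]; sw <- l$stride[2]
  OH <- (d[2] - ph) %/% sh + 1L
  OW <- (d[3] - pw) %/% sw + 1L
  out <- array(-Inf, c(d[1], OH, OW, d[4]))
  arg <- array(0L, c(d[1], OH, OW, d[4]))
  off <- 0L
  for (j in seq_len(pw)) for (i in seq_len(ph)) {
    off <- off + 1L
    slab <- a[, seq(i, by = sh, length.out = OH),
                seq(j, by = sw, length.out = OW), , drop = FALSE]
    m <- slab > out
    out[m] <- slab[m]
    arg[m] <- off
  }
  list(out = out, cache = list(arg = arg, in_dim = d))
}

forward_batchnorm <- function(a, p, st, training, eps = 1e-5, momentum = 0.9) {
  d <- dim(a)
  C <- d[length(d)]
  xm <- matrix(a, prod(d) / C, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    new_mean <- if (is.null(st$mean)) mu else momentum * st$mean + (1 - momentum) * mu
    new_var <- if (is.null(st$var)) v else momentum * st$var + (1 - momentum) * v
    st_out <- list(mean = new_mean, var = new_var)
  } else {
    mu <- st$mean %||% colMeans(xm)
    v <- st$var %||% pmax(colMeans(xm^2) - colMeans(xm)^2, 0)
    st_out <- st
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(out = array(y, d),
       cache = list(xhat = xhat, inv_sd = inv_sd, in_dim = d),
       state = st_out)
}

forward_lstm <- function(x, p, return_sequences) {
  d <- dim(x)
  B <- d[1]; Tn <- d[2]; D <- d[3]
  H <- nrow(p$Wh)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  steps <- vector("list", Tn)
  hs <- if (return_sequences) array(0, c(B, Tn, H)) else NULL
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], B, D)
    z <- xt %*% p$Wx + h %*% p$Wh
    z <- z + rep(p$b, each = B)
    i_g <- sigmoid(z[, 1:H, drop = FALSE])
    f_g <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g_g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o_g <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f_g * cc + i_g * g_g
    tc <- tanh(cc)
    h_prev <- h
    h <- o_g * tc
    steps[[t]] <- list(xt = xt, i = i_g, f = f_g, g = g_g, o = o_g,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
    if (return_sequences) hs[, t, ] <- h
  }
  list(out = if (return_sequences) hs else h,
       cache = list(steps = steps, in_dim = d, H = H,
                    return_sequences = return_sequences))
}

# ---- backward ---------------------------------------------------------

backward_model <- function(model, caches, dout) {
  spec <- model$spec
  grads <- vector("list", length(spec$layers))
  da <- dout
  for (i in rev(seq_along(spec$layers))) {
    l <- spec$layers[[i]]
    p <- model$params[[i]]
    cc <- caches[[i]]
    res <- switch(l$kind,
      conv2d = {
        dA <- matrix(da, prod(dim(da)) / l$filters, l$filters)
        dZ <- dA * (cc$Z > 0)
        g <- list(W = crossprod(cc$P, dZ), b = colSums(dZ))
        dP <- tcrossprod(dZ, p$W)
        list(da = col2im(dP, cc$in_dim, l$kernel[1], l$kernel[2],
                         l$stride[1], l$stride[2]), g = g)
      },
      maxpool2d = {
        d <- cc$in_dim
        dx <- array(0, d)
        OH <- dim(cc$arg)[2]; OW <- dim(cc$arg)[3]
        off <- 0L
        for (j in seq_len(l$pool[2])) for (i2 in seq_len(l$pool[1])) {
          off <- off + 1L
          sel <- (cc$arg == off) * da
          ri <- seq(i2, by = l$stride[1], length.out = OH)
          ci <- seq(j, by = l$stride[2], length.out = OW)
          dx[, ri, ci, ] <- dx[, ri, ci, ] + sel
        }
        list(da = dx, g = NULL)
      },
      batchnorm = {
        d <- cc$in_dim
        C <- d[length(d)]
        n <- prod(d) / C
        dy <- matrix(da, n, C)
        dgamma <- colSums(dy * cc$xhat)
        dbeta <- colSums(dy)
        dxhat <- sweep(dy, 2, p$gamma, `*`)
        mean_dxhat <- colSums(dxhat) / n
        mean_dxhat_xhat <- colSums(dxhat * cc$xhat) / n
        dx <- sweep(dxhat - rep(mean_dxhat, each = n) -
                      cc$xhat * rep(mean_dxhat_xhat, each = n),
                    2, cc$inv_sd, `*`)
        list(da = array(dx, d), g = list(gamma = dgamma, beta = dbeta))
      },
      flatten = list(da = array(da, cc$in_dim), g = NULL),
      flatten_seq = list(da = array(da, cc$in_dim), g = NULL),
      lstm = backward_lstm(da, p, cc),
      dropout = {
        if (is.null(cc$mask)) list(da = da, g = NULL)
        else list(da = da * cc$mask, g = NULL)
      },
      dense = {
        dZ <- switch(l$activation,
          relu = da * (cc$Z > 0),
          linear = da,
          softmax = da)  # caller supplies d(loss)/dZ for the softmax head
        g <- list(W = crossprod(cc$a_in, dZ), b = colSums(dZ))
        list(da = tcrossprod(dZ, p$W), g = g)
      })
    grads[i] <- list(res$g)  # plain [[<- would drop NULL entries and shift indices
    da <- res$da
  }
  grads
}

backward_lstm <- function(dout, p, cc) {
  d <- cc$in_dim
  B <- d[1]; Tn <- d[2]; D <- d[3]; H <- cc$H
  dWx <- matrix(0, D, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dx <- array(0, d)
  dh <- if (cc$return_sequences) matrix(0, B, H) else matrix(dout, B, H)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    s <- cc$steps[[t]]
    if (cc$return_sequences) dh <- dh + matrix(dout[, t, ], B, H)
    do_g <- dh * s$tc
    dcc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dcc * s$g
    dg <- dcc * s$i
    df <- dcc * s$c_prev
    dc <- dcc * s$f
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_g * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- tcrossprod(dz, p$Wx)
    dh <- tcrossprod(dz, p$Wh)
  }
  list(da = dx, g = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- optimization -----------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(w) list(m = w * 0, v = w * 0))
  })
}

adam_step <- function(params, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- opt[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      opt[[i]][[nm]] <- st
    }
  }
  list(params = params, opt = opt)
}

# ---- training ---------------------------------------------------------

onehot <- function(y, classes) {
  idx <- match(y, classes)
  if (anyNA(idx))
    stop_pcg("unknown class label(s): %s",
             paste(unique(y[is.na(idx)]), collapse = ", "),
             class = "pcgnet_invalid_parameter")
  out <- matrix(0, length(y), length(classes))
  out[cbind(seq_along(y), idx)] <- 1
  out
}

slice_batch <- function(x, idx) {
  nd <- length(dim(x))
  switch(as.character(nd),
    "2" = x[idx, , drop = FALSE],
    "3" = x[idx, , , drop = FALSE],
    "4" = x[idx, , , , drop = FALSE],
    stop_pcg("unsupported feature array rank %d", nd, class = "pcgnet_shape_error"))
}

ce_loss <- function(p, y1h) -mean(rowSums(y1h * log(pmax(p, 1e-12))))

eval_loss_acc <- function(model, x, y1h, batch_size = 64) {
  n <- dim(x)[1]
  loss <- 0; correct <- 0
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    p <- forward_model(model, slice_batch(x, idx), training = FALSE)$out
    loss <- loss + ce_loss(p, y1h[idx, , drop = FALSE]) * length(idx)
    correct <- correct + sum(max.col(p, ties.method = "first") ==
                               max.col(y1h[idx, , drop = FALSE], ties.method = "first"))
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train a model on labelled features
#'
#' Minibatch Adam optimization of the categorical cross-entropy, with
#' per-epoch bookkeeping of training (and optionally validation) loss and
#' accuracy.  Epoch-end losses are evaluated in inference mode (dropout
#' off, batch-norm running statistics), so with a zero learning rate the
#' recorded trajectory is constant.  The run is reproducible from
#' `config$seed`.
#'
#' @param spec a [model_spec()].
#' @param x feature array, first axis = examples, remaining axes matching
#'   `spec$input_shape`.
#' @param y character labels (`"normal"`/`"abnormal"`) or a one-hot
#'   matrix with columns (abnormal, normal).
#' @param config a [train_config()]; defaults to the spec's.
#' @param x_val,y_val optional validation data; if absent and
#'   `config$validation_split > 0`, a stratified fraction of the training
#'   data is held out.
#' @param verbose print per-epoch progress.
#' @return a trained `pcg_model`; `$history` is a data frame with one row
#'   per epoch (`epoch`, `train_loss`, `train_acc`, `val_loss`,
#'   `val_acc`) and `$wall_time_s` the elapsed training time.
#' @export
train_model <- function(spec, x, y, config = spec$config,
                        x_val = NULL, y_val = NULL, verbose = FALSE) {
  t_start <- Sys.time()
  classes <- c("abnormal", "normal")
  if (is.matrix(y)) {
    y1h <- y
  } else {
    if (length(unique(y)) < 2)
      stop_pcg("training set must contain both classes",
               class = "pcgnet_invalid_parameter")
    y1h <- onehot(y, classes)
  }
  n <- dim(x)[1]
  if (n != nrow(y1h))
    stop_pcg("x and y disagree on the number of examples",
             class = "pcgnet_invalid_parameter")
  if (!identical(as.integer(dim(x)[-1]), as.integer(spec$input_shape)))
    stop_pcg("feature shape (%s) does not match spec input (%s)",
             paste(dim(x)[-1], collapse = "x"),
             paste(spec$input_shape, collapse = "x"),
             class = "pcgnet_shape_error")

  with_seed(config$seed, {
    if (is.null(x_val) && config$validation_split > 0) {
      hold <- unlist(lapply(split(seq_len(n), max.col(y1h)), function(ix)
        sample(ix, max(1, round(length(ix) * config$validation_split)))))
      x_val <- slice_batch(x, hold)
      y_val1h <- y1h[hold, , drop = FALSE]
      x <- slice_batch(x, setdiff(seq_len(n), hold))
      y1h <- y1h[setdiff(seq_len(n), hold), , drop = FALSE]
      n <- dim(x)[1]
    } else if (!is.null(y_val)) {
      y_val1h <- if (is.matrix(y_val)) y_val else onehot(y_val, classes)
    }

    model <- init_model(spec, seed = stats::runif(1, 1, 2^30))
    opt <- adam_init(model$params)
    step <- 0L
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(n)
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- order_idx[b0:min(b0 + config$batch_size - 1, n)]
        xb <- slice_batch(x, idx)
        yb <- y1h[idx, , drop = FALSE]
        fwd <- forward_model(model, xb, training = TRUE)
        model$state <- fwd$state
        dZ <- (fwd$out - yb) / length(idx)
        grads <- backward_model(model, fwd$caches, dZ)
        step <- step + 1L
        upd <- adam_step(model$params, grads, opt, config$learning_rate, step)
        model$params <- upd$params
        opt <- upd$opt
      }
      tr <- eval_loss_acc(model, x, y1h)
      va <- if (!is.null(x_val)) eval_loss_acc(model, x_val, y_val1h)
            else c(loss = NA_real_, acc = NA_real_)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = tr["loss"], train_acc = tr["acc"],
                                  val_loss = va["loss"], val_acc = va["acc"],
                                  row.names = NULL)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch,
                        tr["loss"], tr["acc"]))
    }
    model$history <- do.call(rbind, hist)
    model$wall_time_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
    model
  })
}

#' Class probabilities for new examples
#'
#' @param model a trained `pcg_model`.
#' @param x feature array matching the model's input shape (a single
#'   example may omit the batch axis).
#' @return an `n x 2` matrix of probabilities with columns
#'   `(abnormal, normal)`; rows sum to 1.
#' @export
predict_proba <- function(model, x) {
  if (length(dim(x)) == length(model$spec$input_shape))
    x <- array(x, c(1, dim(x)))
  if (!identical(as.integer(dim(x)[-1]), as.integer(model$spec$input_shape)))
    stop_pcg("feature shape (%s) does not match model input (%s)",
             paste(dim(x)[-1], collapse = "x"),
             paste(model$spec$input_shape, collapse = "x"),
             class = "pcgnet_shape_error")
  p <- forward_model(model, x, training = FALSE)$out
  colnames(p) <- model$classes
  p
}

#' Predicted class labels
#'
#' Ties are broken toward the first class (`abnormal`).
#'
#' @inheritParams predict_proba
#' @return character vector of `"abnormal"`/`"normal"`.
#' @export
predict_label <- function(model, x) {
  p <- predict_proba(model, x)
  model$classes[max.col(p, ties.method = "first")]
}

#' @export
print.pcg_model <- function(x, ...) {
  trained <- !is.null(x$history)
  cat(sprintf("<pcg_model> %s (%s), %s parameters\n", x$spec$name,
              if (trained) sprintf("trained %d epochs", nrow(x$history)) else "untrained",
              format(count_parameters(x$spec), big.mark = ",")))
  if (trained) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train loss %.4f, train acc %.3f\n",
                last$train_loss, last$train_acc))
  }
  invisible(x)
}

#' Late-fusion ensemble of trained models
#'
#' Averages the class probabilities of independently trained models (e.g.
#' the sequence LSTM and the image CNN), each applied to its own feature
#' representation of the same examples.  This is the simplest reading of
#' a "multimodal" combination of the 1D and 2D streams, provided
#' alongside the single-stream hybrid network.
#'
#' @param models list of trained `pcg_model`s.
#' @param feature_list list (parallel to `models`) of feature arrays over
#'   the same examples in the same order.
#' @return averaged probability matrix with columns `(abnormal, normal)`.
#' @export
fuse_probabilities <- function(models, feature_list) {
  if (length(models) != length(feature_list) || length(models) == 0)
    stop_pcg("models and feature_list must be non-empty and parallel",
             class = "pcgnet_invalid_parameter")
  probs <- Map(predict_proba, models, feature_list)
  n <- unique(vapply(probs, nrow, integer(1)))
  if (length(n) != 1)
    stop_pcg("feature arrays disagree on the number of examples",
             class = "pcgnet_invalid_parameter")
  Reduce(`+`, probs) / length(probs)
}
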