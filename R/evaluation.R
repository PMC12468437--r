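# Confusion-matrix metrics and evaluation protocols.
#
# The positive class is "abnormal" (the patient class): TP counts patients
# correctly identified, TN healthy subjects correctly cleared.  Four
# headline metrics are reported per evaluation:
#   Acc  = (TP + TN) / (TP + FP + TN + FN)
#   Se   = TP / (TP + FN)
#   Sp   = TN / (FP + TN)
#   MAcc = (Sp + Se) / 2
# Zero-denominator cases yield NA (an explicit undefined marker) and are
# excluded, with a count, from protocol averages.

PCG_CLASSES <- c("abnormal", "normal")

#' Confusion matrix for two-class heart-sound labels
#'
#' @param labels true labels (`"abnormal"`/`"normal"`).
#' @param predictions predicted labels, same length.
#' @return a list of class `confusion_matrix` with counts `TP`, `FN`,
#'   `FP`, `TN` (positive class = abnormal).
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) == 0)
    stop_pcg("empty label vector", class = "pcgnet_invalid_parameter")
  if (length(labels) != length(predictions))
    stop_pcg("labels (%d) and predictions (%d) differ in length",
             length(labels), length(predictions),
             class = "pcgnet_invalid_parameter")
  bad <- setdiff(unique(c(labels, predictions)), PCG_CLASSES)
  if (length(bad))
    stop_pcg("unknown class token(s): %s", paste(bad, collapse = ", "),
             class = "pcgnet_invalid_parameter")
  pos <- labels == "abnormal"
  ppos <- predictions == "abnormal"
  structure(list(TP = sum(pos & ppos), FN = sum(pos & !ppos),
                 FP = sum(!pos & ppos), TN = sum(!pos & !ppos)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(true = c("abnormal", "normal"),
                              predicted = c("abnormal", "normal")))
  print(m)
  invisible(x)
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Modified accuracy from sensitivity and specificity
#'
#' The balanced screening metric: the arithmetic mean of sensitivity
#' (fraction of patients detected) and specificity (fraction of healthy
#' subjects cleared).
#'
#' @param se sensitivity.
#' @param sp specificity.
#' @return `(sp + se) / 2`, or `NA` if either input is `NA`.
#' @export
modified_accuracy <- function(se, sp) {
  if (is.na(se) || is.na(sp)) return(NA_real_)
  (sp + se) / 2
}

#' Derive metrics from a confusion matrix
#'
#' @param cm a [confusion()] result.
#' @return a list of class `pcg_metrics`: `Acc`, `Se`, `Sp`, `MAcc`, plus
#'   per-class `precision`, `recall` and `f1` (named `Ab`, `N`).
#'   Zero-denominator quantities are `NA`.
#' @export
compute_metrics <- function(cm) {
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0)
    stop_pcg("confusion matrix is empty", class = "pcgnet_invalid_parameter")
  se <- safe_div(cm$TP, cm$TP + cm$FN)
  sp <- safe_div(cm$TN, cm$FP + cm$TN)
  prec_ab <- safe_div(cm$TP, cm$TP + cm$FP)
  prec_n <- safe_div(cm$TN, cm$TN + cm$FN)
  rec_ab <- se
  rec_n <- sp
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  structure(list(
    Acc = (cm$TP + cm$TN) / total,
    Se = se, Sp = sp,
    MAcc = modified_accuracy(se, sp),
    precision = c(Ab = prec_ab, N = prec_n),
    recall = c(Ab = rec_ab, N = rec_n),
    f1 = c(Ab = f1(prec_ab, rec_ab), N = f1(prec_n, rec_n)),
    n = total
  ), class = "pcg_metrics")
}

#' @export
print.pcg_metrics <- function(x, ...) {
  cat(sprintf("Acc %.4f  Se %.4f  Sp %.4f  MAcc %.4f  (n=%d)\n",
              x$Acc, x$Se, x$Sp, x$MAcc, x$n))
  invisible(x)
}

#' Per-class precision and F1 from labels and predictions
#'
#' @inheritParams confusion
#' @return a data frame with rows `Ab` (abnormal) and `N` (normal) and
#'   columns `precision`, `recall`, `f1`.
#' @export
precision_f1 <- function(labels, predictions) {
  m <- compute_metrics(confusion(labels, predictions))
  data.frame(class = c("Ab", "N"),
             precision = unname(m$precision),
             recall = unname(m$recall),
             f1 = unname(m$f1))
}

# Stratified fold ids: within each class, shuffled records are dealt
# round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(y, k, seed) {
  if (k > length(y))
    stop_pcg("k (%d) exceeds the number of examples (%d)", k, length(y),
             class = "pcgnet_invalid_parameter")
  if (k < 2)
    stop_pcg("k must be at least 2", class = "pcgnet_invalid_parameter")
  folds <- integer(length(y))
  with_seed(derive_seed(seed, 77L), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

mean_metrics <- function(metric_list) {
  fields <- c("Acc", "Se", "Sp", "MAcc")
  means <- sapply(fields, function(f) {
    v <- vapply(metric_list, function(m) m[[f]], numeric(1))
    mean(v, na.rm = TRUE)
  })
  sds <- sapply(fields, function(f) {
    v <- vapply(metric_list, function(m) m[[f]], numeric(1))
    stats::sd(v, na.rm = TRUE)
  })
  undefined <- sum(vapply(metric_list, function(m)
    anyNA(c(m$Se, m$Sp)), logical(1)))
  list(mean = means, sd = sds, n_undefined = undefined)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the examples into k stratified folds (fold sizes differ by
#' at most one per class), trains a fresh model on each training portion,
#' and evaluates on the held-out fold, so every example is tested exactly
#' once.
#'
#' @param x feature array (first axis = examples).
#' @param y character labels.
#' @param model_builder function `(input_shape) -> model_spec`.
#' @param k number of folds (default 10).
#' @param config optional [train_config()] overriding each spec's own.
#' @param seed seed controlling fold assignment and per-fold training.
#' @return a list of class `cv_report`: `fold_metrics` (list of
#'   [compute_metrics()] results), `folds` (assignment vector), `summary`
#'   (mean and sd of Acc/Se/Sp/MAcc over folds, with the count of folds
#'   where a metric was undefined).
#' @export
kfold_cv <- function(x, y, model_builder, k = 10, config = NULL, seed = 1L) {
  folds <- stratified_folds(y, k, seed)
  input_shape <- dim(x)[-1]
  fold_metrics <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    spec <- model_builder(input_shape)
    cfg <- config %||% spec$config
    cfg$seed <- derive_seed(seed, 1000L + f)
    fit <- train_model(spec, slice_batch(x, train_idx), y[train_idx], cfg)
    pred <- predict_label(fit, slice_batch(x, test_idx))
    fold_metrics[[f]] <- compute_metrics(confusion(y[test_idx], pred))
  }
  structure(list(fold_metrics = fold_metrics, folds = folds,
                 summary = mean_metrics(fold_metrics), k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_report> k=%d: Acc %.4f+/-%.4f  Se %.4f  Sp %.4f  MAcc %.4f\n",
              x$k, s$mean["Acc"], s$sd["Acc"], s$mean["Se"], s$mean["Sp"],
              s$mean["MAcc"]))
  if (s$n_undefined > 0)
    cat(sprintf("  (%d fold(s) had an undefined metric, excluded from means)\n",
                s$n_undefined))
  invisible(x)
}

#' Repeated balanced-resampling evaluation protocol
#'
#' The full protocol: each iteration draws a balanced subset
#' (`n_per_class` per class, without replacement via
#' [balanced_resample()]), runs stratified k-fold cross-validation on it,
#' and records the fold-averaged metrics; the report aggregates mean and
#' standard deviation over iterations.  Defaults mirror the headline
#' protocol (218 + 218 signals, 50 iterations, 10 folds); scaled-down
#' settings run in seconds.
#'
#' @param x feature array for the whole pool.
#' @param y pool labels.
#' @param model_builder function `(input_shape) -> model_spec`.
#' @param n_per_class examples drawn per class per iteration.
#' @param iterations number of balanced draws.
#' @param k folds per iteration.
#' @param config optional [train_config()] override.
#' @param seed master seed.
#' @param replace allow drawing with replacement when the pool is small.
#' @return a list of class `protocol_report`: `iteration_summaries` (per
#'   iteration mean metrics), `grand` (mean and sd across iterations),
#'   `n_per_class`, `iterations`.
#' @export
repeated_protocol <- function(x, y, model_builder, n_per_class = 218,
                              iterations = 50, k = 10, config = NULL,
                              seed = 1L, replace = FALSE) {
  pool <- as_manifest(data.frame(path = as.character(seq_along(y)), label = y,
                                 stringsAsFactors = FALSE))
  draws <- balanced_resample(pool, n_per_class = n_per_class,
                             iterations = iterations, seed = seed,
                             replace = replace)
  iter_means <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    idx <- as.integer(draws[[it]]$path)
    cv <- kfold_cv(slice_batch(x, idx), y[idx], model_builder, k = k,
                   config = config, seed = derive_seed(seed, 500000L + it))
    iter_means[[it]] <- as.list(cv$summary$mean)
  }
  fields <- c("Acc", "Se", "Sp", "MAcc")
  mat <- sapply(fields, function(f)
    vapply(iter_means, function(m) m[[f]], numeric(1)))
  mat <- matrix(mat, nrow = iterations,
                dimnames = list(NULL, fields))
  structure(list(iteration_summaries = as.data.frame(mat),
                 grand = list(mean = colMeans(mat, na.rm = TRUE),
                              sd = apply(mat, 2, stats::sd, na.rm = TRUE)),
                 n_per_class = n_per_class, iterations = iterations, k = k,
                 seed = seed),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  g <- x$grand
  cat(sprintf("<protocol_report> %d iterations x %d-fold on %d+%d draws\n",
              x$iterations, x$k, x$n_per_class, x$n_per_class))
  cat(sprintf("  Acc %.4f+/-%.4f  Se %.4f  Sp %.4f  MAcc %.4f\n",
              g$mean["Acc"], g$sd["Acc"], g$mean["Se"], g$mean["Sp"],
              g$mean["MAcc"]))
  invisible(x)
}

#' Paired comparison of feature extractors
#'
#' Featurizes the same corpus under each extractor, applies the identical
#' stratified split and the identical convolutional head, and reports
#' per-class precision/F1 and test accuracy per extractor, so differences
#' are attributable to the extractor alone.
#'
#' @param manifest a `dataset_manifest` of WAV recordings.
#' @param extractors character vector from `"mfcc"`, `"stft"`,
#'   `"wavelet"`.
#' @param model_builder function `(input_shape) -> model_spec` (the fixed
#'   head).
#' @param config optional [train_config()] override.
#' @param image_size image size passed to every extractor.
#' @param seed seed fixing the shared split and training.
#' @param ratios split ratios (train/validation/test).
#' @return a data frame with one row per extractor: precision and F1 per
#'   class and test accuracy.
#' @export
compare_extractors <- function(manifest, extractors, model_builder,
                               config = NULL, image_size = c(64, 64),
                               seed = 1L, ratios = c(0.8, 0.1, 0.1)) {
  if (length(extractors) == 0)
    stop_pcg("at least one extractor is required", class = "pcgnet_invalid_parameter")
  manifest <- as_manifest(manifest)
  split <- stratified_split(manifest, ratios, seed = seed)
  if (!any(split$partition == "test"))
    stop_pcg("the split allocates no test records (corpus too small for ratios %s)",
             paste(ratios, collapse = ":"), class = "pcgnet_invalid_parameter")
  rows <- lapply(extractors, function(ex) {
    cfg_feat <- feature_config(ex, image_size = image_size)
    data <- featurize_manifest(split, cfg_feat, mode = "image")
    tr <- split$partition != "test"
    te <- split$partition == "test"
    spec <- model_builder(dim(data$x)[-1])
    cfg <- config %||% spec$config
    cfg$seed <- derive_seed(seed, 42L)
    fit <- train_model(spec, slice_batch(data$x, which(tr)), data$y[tr], cfg)
    pred <- predict_label(fit, slice_batch(data$x, which(te)))
    pf <- precision_f1(data$y[te], pred)
    acc <- mean(pred == data$y[te])
    data.frame(extractor = ex,
               precision_Ab = pf$precision[1], precision_N = pf$precision[2],
               f1_Ab = pf$f1[1], f1_N = pf$f1[2],
               test_accuracy = acc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Training-cost report
#'
#' Tabulates, per model, the closed-form trainable parameter count
#' together with the epochs, batch size and wall-clock time actually used
#' in training; rows are sorted by parameter count, largest first.
#'
#' @param specs list of [model_spec()]s.
#' @param histories optional list (parallel to `specs`) of trained
#'   `pcg_model`s or `NULL`s supplying epochs trained and wall time.
#' @return a data frame with columns `model`, `parameters`, `epochs`,
#'   `batch_size`, `train_time_s`.
#' @export
cost_report <- function(specs, histories = NULL) {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    h <- if (!is.null(histories)) histories[[i]] else NULL
    data.frame(model = s$name,
               parameters = count_parameters(s),
               epochs = if (!is.null(h)) nrow(h$history) else s$config$epochs,
               batch_size = s$config$batch_size,
               train_time_s = if (!is.null(h)) h$wall_time_s else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$parameters), , drop = FALSE]
}
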