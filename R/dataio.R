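# Manifest handling, windowing, and the sampling protocols:
# an 80/10/10 stratified split and a repeated balanced-resampling scheme
# that draws equal-sized class subsets for cross-validated evaluation.

#' Read a dataset manifest from CSV
#'
#' @param path CSV with at least `path` and `label` columns
#'   (labels `normal`/`abnormal`).
#' @return a `dataset_manifest` data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_pcg("manifest not found: %s", path, class = "pcgnet_io_error")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_manifest(m)
}

#' Validate a data frame as a dataset manifest
#'
#' Checks path uniqueness and the two-class label restriction.
#'
#' @param m a data frame with `path` and `label` columns.
#' @return `m` with class `dataset_manifest`.
#' @export
as_manifest <- function(m) {
  if (!all(c("path", "label") %in% names(m)))
    stop_pcg("manifest must have `path` and `label` columns",
             class = "pcgnet_invalid_parameter")
  if (anyDuplicated(m$path))
    stop_pcg("manifest paths must be unique", class = "pcgnet_invalid_parameter")
  bad <- setdiff(unique(m$label), c("normal", "abnormal"))
  if (length(bad))
    stop_pcg("labels must be 'normal' or 'abnormal' (found: %s)",
             paste(bad, collapse = ", "), class = "pcgnet_invalid_parameter")
  class(m) <- unique(c("dataset_manifest", class(m)))
  m
}

#' Class counts of a manifest
#' @param m a `dataset_manifest`.
#' @return named integer vector of counts per label.
#' @export
class_counts <- function(m) {
  c(normal = sum(m$label == "normal"), abnormal = sum(m$label == "abnormal"))
}

#' Cut a recording into fixed-length windows
#'
#' Emits consecutive full windows of `window_s` seconds with stride
#' `window_s - overlap_s`; an incomplete tail is discarded rather than
#' padded, so every emitted segment is statistically homogeneous.  Each
#' segment inherits the recording's label and condition.
#'
#' @param recording a [pcg_recording].
#' @param window_s window length in seconds (default 6).
#' @param overlap_s overlap between consecutive windows, `0 <= overlap_s <
#'   window_s`.
#' @return a list of `audio_segment` objects (possibly empty).
#' @export
segment_recording <- function(recording, window_s = 6, overlap_s = 0) {
  check_positive(window_s, "window_s")
  if (overlap_s < 0 || overlap_s >= window_s)
    stop_pcg("overlap_s must satisfy 0 <= overlap_s < window_s",
             class = "pcgnet_invalid_parameter")
  sr <- recording$sample_rate
  win <- round(window_s * sr)
  hop <- round((window_s - overlap_s) * sr)
  n <- length(recording$samples)
  starts <- seq(1L, by = hop, length.out = max(0L, 1L + floor((n - win) / hop)))
  if (n < win) starts <- integer(0)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    structure(list(samples = recording$samples[s:(s + win - 1L)],
                   sample_rate = sr,
                   source_path = recording$source_path %||% NA_character_,
                   window_index = i,
                   label = recording$label,
                   condition = recording$condition),
              class = c("audio_segment", "pcg_recording"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/validation/test split
#'
#' Allocates each class across the three partitions by largest-remainder
#' rounding of `ratios` (ties broken by partition order train, validation,
#' test), then assigns shuffled records; the shuffle is reproducible under
#' `seed`.  With the study corpus (30/30) and the default 8:1:1 ratios this
#' yields 48/6/6 records with both classes balanced in every partition.
#'
#' @param manifest a `dataset_manifest`.
#' @param ratios three fractions summing to 1.
#' @param seed integer seed.
#' @return the manifest with an added `partition` column
#'   (`train`/`validation`/`test`).
#' @export
stratified_split <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9)
    stop_pcg("ratios must be three fractions summing to 1",
             class = "pcgnet_invalid_parameter")
  manifest <- as_manifest(manifest)
  parts <- c("train", "validation", "test")
  manifest$partition <- NA_character_
  for (cls in sort(unique(manifest$label))) {
    idx <- which(manifest$label == cls)
    n <- length(idx)
    exact <- n * ratios
    base <- floor(exact)
    rem <- exact - base
    short <- n - sum(base)
    if (short > 0) {
      order_rem <- order(-rem, seq_along(rem))  # largest remainder, then partition order
      base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
    }
    shuffled <- with_seed(derive_seed(seed, match(cls, c("abnormal", "normal"))),
                          sample(idx))
    assignment <- rep(parts, times = base)
    manifest$partition[shuffled] <- assignment
  }
  manifest
}

#' Repeated balanced resampling of a pool
#'
#' For each of `iterations` draws, selects `n_per_class` normal and
#' `n_per_class` abnormal records without replacement within the draw
#' (defaults 218 + 218 over 50 iterations).  Draws are independent given
#' `seed`.
#'
#' @param pool a `dataset_manifest` (typically of windowed segments).
#' @param n_per_class records drawn per class per iteration.
#' @param iterations number of draws.
#' @param seed integer seed.
#' @param replace draw with replacement (needed when a class has fewer than
#'   `n_per_class` members).
#' @return a list of `iterations` balanced `dataset_manifest`s.
#' @export
balanced_resample <- function(pool, n_per_class = 218, iterations = 50,
                              seed = 1L, replace = FALSE) {
  pool <- as_manifest(pool)
  check_positive(n_per_class, "n_per_class")
  check_positive(iterations, "iterations")
  cc <- class_counts(pool)
  if (!replace) {
    deficient <- names(cc)[cc < n_per_class]
    if (length(deficient))
      stop_pcg("class '%s' has only %d records but %d per class were requested (set replace = TRUE to allow resampling)",
               deficient[1], cc[deficient[1]], n_per_class,
               class = "pcgnet_capacity_error")
  }
  idx_by_class <- split(seq_len(nrow(pool)), pool$label)
  lapply(seq_len(iterations), function(it) {
    with_seed(derive_seed(seed, it), {
      take <- unlist(lapply(idx_by_class[c("normal", "abnormal")], function(ix)
        sample(ix, n_per_class, replace = replace)), use.names = FALSE)
      sub <- pool[take, , drop = FALSE]
      rownames(sub) <- NULL
      class(sub) <- class(pool)
      sub
    })
  })
}
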