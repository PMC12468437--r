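# Time-frequency feature extraction.
#
# Three extractors share one framing convention:
#   n_frames = 1 + floor((N - frame_samples) / hop_samples).
# MFCC yields the 1D sequence representation (frames x coefficients) fed
# to recurrent models; all three can be rendered as fixed-size HxWx3
# images in [0,1] for the convolutional models.

#' Feature extraction configuration
#'
#' @param extractor `"mfcc"`, `"stft"` or `"wavelet"`.
#' @param frame_length_s analysis frame length in seconds (default 25 ms).
#' @param hop_length_s hop between frames (default 10 ms); must not exceed
#'   the frame length.
#' @param n_mfcc number of cepstral coefficients kept.
#' @param n_mels number of mel filters.
#' @param n_fft FFT length; `NULL` selects the next power of two at or
#'   above the frame length.
#' @param n_scales number of wavelet scales (log-spaced over ~20 Hz to
#'   Nyquist).
#' @param image_size `(H, W)` of rendered images; each side at least 8.
#' @param log_floor positive floor applied before every logarithm so that
#'   silent input never produces `-Inf`.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(extractor = c("mfcc", "stft", "wavelet"),
                           frame_length_s = 0.025, hop_length_s = 0.010,
                           n_mfcc = 13, n_mels = 26, n_fft = NULL,
                           n_scales = 64, image_size = c(128, 128),
                           log_floor = 1e-10) {
  extractor <- match.arg(extractor)
  if (hop_length_s > frame_length_s)
    stop_pcg("hop_length_s must not exceed frame_length_s",
             class = "pcgnet_invalid_parameter")
  if (any(image_size < 8))
    stop_pcg("image_size sides must be >= 8", class = "pcgnet_invalid_parameter")
  check_positive(log_floor, "log_floor")
  structure(list(extractor = extractor, frame_length_s = frame_length_s,
                 hop_length_s = hop_length_s, n_mfcc = n_mfcc, n_mels = n_mels,
                 n_fft = n_fft, n_scales = n_scales,
                 image_size = image_size, log_floor = log_floor),
            class = "feature_config")
}

frame_signal <- function(x, frame, hop) {
  n <- length(x)
  if (n < frame)
    stop_pcg("signal (%d samples) shorter than one frame (%d samples)",
             n, frame, class = "pcgnet_empty_feature")
  n_frames <- 1L + floor((n - frame) / hop)
  idx <- outer(seq_len(frame), (seq_len(n_frames) - 1L) * hop, `+`)
  matrix(x[idx], nrow = frame, ncol = n_frames)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Mel scale (HTK convention)
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filterbank matrix
#'
#' Triangular filters equally spaced on the mel scale between 0 Hz and
#' Nyquist, returned as an `n_mels x n_bins` matrix acting on one-sided
#' power spectra.
#'
#' @param n_mels number of filters.
#' @param n_fft FFT length (one-sided spectrum has `n_fft/2 + 1` bins).
#' @param sample_rate Hz.
#' @return the filterbank matrix.
#' @export
mel_filterbank <- function(n_mels, n_fft, sample_rate) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sample_rate / n_fft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                         length.out = n_mels + 2))
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- edges[m]; ctr <- edges[m + 1]; hi <- edges[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_ii_matrix <- function(n_out, n_in) {
  # orthonormal DCT-II, rows = coefficients
  d <- outer(seq_len(n_out) - 1, seq_len(n_in) - 0.5,
             function(k, j) cos(pi * k * j / n_in))
  d <- d * sqrt(2 / n_in)
  d[1, ] <- d[1, ] / sqrt(2)
  d
}

power_spectrum <- function(recording, config) {
  sr <- recording$sample_rate
  frame <- round(config$frame_length_s * sr)
  hop <- round(config$hop_length_s * sr)
  n_fft <- config$n_fft %||% next_pow2(frame)
  if (n_fft < frame)
    stop_pcg("n_fft (%d) must be at least the frame length (%d samples)",
             n_fft, frame, class = "pcgnet_invalid_parameter")
  frames <- frame_signal(recording$samples, frame, hop)
  win <- signal::hanning(frame)
  frames <- frames * win
  if (n_fft > frame)
    frames <- rbind(frames, matrix(0, n_fft - frame, ncol(frames)))
  spec <- stats::mvfft(frames)[seq_len(n_fft %/% 2 + 1), , drop = FALSE]
  list(power = Mod(spec)^2, n_fft = n_fft, hop = hop, frame = frame, sr = sr)
}

#' Mel-frequency cepstral coefficient sequence
#'
#' Frames the signal (Hann window), takes the one-sided power spectrum,
#' applies a mel filterbank, logs the filter energies (floored at
#' `log_floor`), and projects onto the first `n_mfcc` orthonormal DCT-II
#' basis vectors.
#'
#' @param recording a [pcg_recording] or audio segment.
#' @param config a [feature_config()].
#' @return a `sequence_features` object: `values` is an
#'   `n_frames x n_mfcc` matrix, `frame_times` the frame start times in
#'   seconds, `label` inherited from the recording.
#' @export
compute_mfcc <- function(recording, config = feature_config()) {
  ps <- power_spectrum(recording, config)
  fb <- mel_filterbank(config$n_mels, ps$n_fft, ps$sr)
  logmel <- log(pmax(fb %*% ps$power, config$log_floor))
  dct <- dct_ii_matrix(config$n_mfcc, config$n_mels)
  values <- t(dct %*% logmel)                     # frames x coefficients
  structure(list(values = values,
                 frame_times = (seq_len(nrow(values)) - 1) * ps$hop / ps$sr,
                 label = recording$label),
            class = "sequence_features")
}

#' STFT magnitude spectrogram
#'
#' @inheritParams compute_mfcc
#' @return non-negative magnitude matrix, frequencies (0..Nyquist) by
#'   frames, with attributes `freqs` and `times`.
#' @export
compute_stft_spectrogram <- function(recording, config = feature_config("stft")) {
  ps <- power_spectrum(recording, config)
  mag <- sqrt(ps$power)
  structure(mag,
            freqs = (seq_len(nrow(mag)) - 1) * ps$sr / ps$n_fft,
            times = (seq_len(ncol(mag)) - 1) * ps$hop / ps$sr)
}

#' Continuous Morlet wavelet scalogram
#'
#' FFT-based continuous wavelet transform with an analytic Morlet mother
#' wavelet (shape parameter 6).  Scales are log-spaced so that their
#' center frequencies cover 20 Hz to Nyquist; magnitudes are sampled every
#' hop to give a time axis matching the other extractors.
#'
#' @inheritParams compute_mfcc
#' @return non-negative magnitude matrix, scales (low to high frequency)
#'   by time, with attributes `freqs` (center frequency per row) and
#'   `times`.
#' @export
compute_wavelet_scalogram <- function(recording, config = feature_config("wavelet")) {
  if (config$n_scales < 2)
    stop_pcg("n_scales must be >= 2", class = "pcgnet_invalid_parameter")
  x <- recording$samples
  sr <- recording$sample_rate
  n <- length(x)
  hop <- round(config$hop_length_s * sr)
  if (n < hop)
    stop_pcg("signal shorter than one hop", class = "pcgnet_empty_feature")
  omega0 <- 6
  freqs <- exp(seq(log(20), log(sr / 2), length.out = config$n_scales))
  scales <- omega0 * sr / (2 * pi * freqs)        # in samples

  m <- next_pow2(2L * n)
  xf <- stats::fft(c(x, numeric(m - n)))
  w <- 2 * pi * (seq_len(m) - 1) / m              # angular frequency grid
  pos <- w <= pi                                  # analytic wavelet: positive freqs only
  out_idx <- seq(1L, n, by = hop)
  mag <- matrix(0, config$n_scales, length(out_idx))
  for (s in seq_along(scales)) {
    psi_hat <- numeric(m)
    psi_hat[pos] <- pi^(-0.25) * sqrt(2 * pi * scales[s]) *
      exp(-((scales[s] * w[pos] - omega0)^2) / 2)
    conv <- stats::fft(xf * psi_hat, inverse = TRUE) / m
    mag[s, ] <- Mod(conv[out_idx])
  }
  structure(mag, freqs = freqs, times = (out_idx - 1) / sr)
}

#' Render a feature matrix as a fixed-size image
#'
#' Optionally log-compresses (floored at `log_floor`), resizes bilinearly
#' to `image_size`, min-max normalizes to `[0,1]` (a constant matrix maps
#' to all zeros), and replicates the result onto three identical
#' channels.  Normalization happens after the resize so every non-constant
#' image spans the full `[0, 1]` range.
#'
#' @param m a non-empty numeric matrix.
#' @param image_size target `(H, W)`.
#' @param log_floor floor for the log compression.
#' @param log_compress apply log compression first (appropriate for
#'   magnitude matrices; disable for matrices already in a log domain,
#'   e.g. MFCCs).
#' @return an `H x W x 3` array with values in `[0, 1]`.
#' @export
to_image <- function(m, image_size = c(128, 128), log_floor = 1e-10,
                     log_compress = TRUE) {
  m <- unclass(m)
  if (is.null(dim(m)) || any(dim(m) == 0) || length(m) == 0)
    stop_pcg("feature matrix is empty", class = "pcgnet_invalid_parameter")
  if (log_compress) m <- log(pmax(m, log_floor))
  resized <- EBImage::resize(EBImage::Image(m), w = image_size[1], h = image_size[2])
  px <- EBImage::imageData(resized)
  # normalize after resizing so the emitted image always spans [0, 1]
  # exactly (downsampling first would clip the extremes away)
  rng <- range(px)
  px <- if (rng[2] > rng[1]) (px - rng[1]) / (rng[2] - rng[1]) else px * 0
  array(px, dim = c(image_size[1], image_size[2], 3))
}

#' Image representation of a recording under a chosen extractor
#'
#' Applies the configured extractor and renders the resulting matrix via
#' [to_image()].  MFCC matrices skip log compression (they are already
#' cepstral); STFT and wavelet magnitudes are log-compressed.
#'
#' @inheritParams compute_mfcc
#' @return an `H x W x 3` array in `[0, 1]`.
#' @export
image_features <- function(recording, config = feature_config("stft")) {
  m <- switch(config$extractor,
    mfcc = t(compute_mfcc(recording, config)$values),  # coefficients x frames
    stft = compute_stft_spectrogram(recording, config),
    wavelet = compute_wavelet_scalogram(recording, config))
  to_image(m, config$image_size, config$log_floor,
           log_compress = config$extractor != "mfcc")
}

#' Featurize every record in a manifest
#'
#' Reads each WAV, applies the extractor, and stacks results into a single
#' array suitable for [train_model()]: sequences give
#' `(n, timesteps, coefficients)`, images give `(n, H, W, 3)`.
#'
#' @param manifest a `dataset_manifest`.
#' @param config a [feature_config()].
#' @param mode `"sequence"` (MFCC frames for recurrent models) or
#'   `"image"` (rendered images for convolutional models).
#' @return list with `x` (feature array), `y` (labels), `manifest`.
#' @export
featurize_manifest <- function(manifest, config = feature_config(),
                               mode = c("sequence", "image")) {
  mode <- match.arg(mode)
  manifest <- as_manifest(manifest)
  feats <- lapply(manifest$path, function(p) {
    rec <- read_wav(p)
    if (mode == "sequence") compute_mfcc(rec, config)$values
    else image_features(rec, config)
  })
  d <- dim(feats[[1]])
  x <- array(0, dim = c(length(feats), d))
  for (i in seq_along(feats)) {
    if (length(d) == 2) x[i, , ] <- feats[[i]] else x[i, , , ] <- feats[[i]]
  }
  list(x = x, y = manifest$label, manifest = manifest)
}
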