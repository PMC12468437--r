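tone <- function(freq, dur = 1, sr = 4000, amp = 0.5) {
  pcg_recording(amp * sin(2 * pi * freq * (0:(dur * sr - 1)) / sr), sr)
}

test_that("framing arithmetic matches the closed form for random lengths", {
  set.seed(8)
  cfg <- feature_config()
  for (rep in 1:6) {
    n <- sample(200:9000, 1)
    rec <- pcg_recording(stats::rnorm(n) / 10, 4000)
    frame <- round(cfg$frame_length_s * 4000); hop <- round(cfg$hop_length_s * 4000)
    if (n < frame) {
      expect_error(compute_mfcc(rec, cfg), class = "pcgnet_empty_feature")
    } else {
      f <- compute_mfcc(rec, cfg)
      expect_equal(nrow(f$values), 1 + floor((n - frame) / hop))
      expect_equal(ncol(f$values), cfg$n_mfcc)
      expect_true(all(is.finite(f$values)))
    }
  }
  # the documented case: 6 s at 4000 Hz, 25 ms frames, 10 ms hop
  f6 <- compute_mfcc(tone(100, 6), cfg)
  expect_equal(nrow(f6$values), 598)
})

test_that("all-zero input yields constant finite MFCC frames", {
  rec <- pcg_recording(numeric(4000), 4000)
  f <- compute_mfcc(rec)
  expect_true(all(is.finite(f$values)))
  expect_equal(max(apply(f$values, 2, stats::sd)), 0)
})

test_that("mel filterbank localizes a pure tone in the expected filter", {
  sr <- 4000; n_fft <- 128
  fb <- mel_filterbank(26, n_fft, sr)
  # oracle: the filter whose response at the 300 Hz bin is maximal must be
  # the filter with peak (center) frequency nearest 300 Hz
  freqs <- (0:(n_fft / 2)) * sr / n_fft
  bin300 <- which.min(abs(freqs - 300))
  resp <- fb[, bin300]
  centers <- apply(fb, 1, function(r) freqs[which.max(r)])
  expect_equal(which.max(resp), which.min(abs(centers - 300)))

  # end to end: a 300 Hz tone maximizes energy in that same filter
  cfg <- feature_config(n_fft = 128)
  ps <- pcgnet:::power_spectrum(tone(300), cfg)
  mel_e <- rowMeans(mel_filterbank(26, 128, sr) %*% ps$power)
  expect_equal(which.max(mel_e), which.min(abs(centers - 300)))
})

test_that("STFT localizes tones at the analytic bin and scales with energy", {
  cfg <- feature_config("stft", n_fft = 256)
  rec <- tone(500)
  mag <- compute_stft_spectrogram(rec, cfg)
  expect_true(all(mag >= 0))
  expected_bin <- round(500 * 256 / 4000) + 1
  argmaxes <- apply(mag, 2, which.max)
  expect_true(all(argmaxes == expected_bin))
  # doubling the amplitude quadruples total power
  mag2 <- compute_stft_spectrogram(tone(500, amp = 1.0), cfg)
  expect_equal(sum(mag2^2) / sum(mag^2), 4, tolerance = 1e-8)
  # zero input gives a zero matrix
  z <- compute_stft_spectrogram(pcg_recording(numeric(4000), 4000), cfg)
  expect_equal(max(z), 0)
})

test_that("scalogram maps lower tones to larger scales and shifts with the signal", {
  cfg <- feature_config("wavelet", n_scales = 48)
  m100 <- compute_wavelet_scalogram(tone(100, 2), cfg)
  m400 <- compute_wavelet_scalogram(tone(400, 2), cfg)
  freqs <- attr(m100, "freqs")
  r100 <- which.max(rowMeans(m100))
  r400 <- which.max(rowMeans(m400))
  expect_lt(freqs[r100], freqs[r400])          # rows are low->high frequency
  expect_lt(abs(freqs[r100] - 100) / 100, 0.25)
  expect_lt(abs(freqs[r400] - 400) / 400, 0.25)

  # a shifted transient shifts the scalogram along time
  sr <- 2000; hop <- round(0.01 * sr)
  base <- numeric(2 * sr)
  burst <- synth_transient(150, 0.1, 1, sr)
  x1 <- base; x1[401:(400 + length(burst))] <- burst
  shift_cols <- 20                              # 20 hops = 0.2 s
  x2 <- base; x2[(401 + shift_cols * hop):(400 + shift_cols * hop + length(burst))] <- burst
  s1 <- compute_wavelet_scalogram(pcg_recording(x1, sr), cfg)
  s2 <- compute_wavelet_scalogram(pcg_recording(x2, sr), cfg)
  row <- which.max(rowMeans(s1))
  expect_equal(which.max(s2[row, ]) - which.max(s1[row, ]), shift_cols)

  z <- compute_wavelet_scalogram(pcg_recording(numeric(2000), 2000), cfg)
  expect_equal(max(z), 0)
})

test_that("to_image yields unit-range three-channel images of the requested size", {
  m <- matrix(stats::runif(64 * 40), 64, 40)
  img <- to_image(m, c(128, 128))
  expect_equal(dim(img), c(128, 128, 3))
  expect_equal(min(img), 0)
  expect_equal(max(img), 1)
  expect_identical(img[, , 1], img[, , 3])
  # constant input maps to all zeros by convention
  expect_equal(max(to_image(matrix(2, 10, 10), c(16, 16))), 0)
  expect_error(to_image(matrix(numeric(0), 0, 0)), class = "pcgnet_invalid_parameter")
})

test_that("extractors are deterministic and interchangeable as image sources", {
  rec <- synthesize_recording("PS", 85, 3, 4000, seed = 14)
  for (ex in c("mfcc", "stft", "wavelet")) {
    cfg <- feature_config(ex, image_size = c(32, 32))
    a <- image_features(rec, cfg)
    b <- image_features(rec, cfg)
    expect_identical(a, b)
    expect_equal(dim(a), c(32, 32, 3))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("featurize_manifest stacks features aligned with labels", {
  manifest <- study_corpus()[c(1:3, 31:33), ]
  class(manifest) <- c("dataset_manifest", "data.frame")
  seqs <- featurize_manifest(manifest,
                             feature_config(frame_length_s = 0.05, hop_length_s = 0.05),
                             mode = "sequence")
  expect_equal(dim(seqs$x)[1], 6)
  expect_equal(dim(seqs$x)[3], 13)
  expect_equal(seqs$y, manifest$label)
  imgs <- featurize_manifest(manifest, feature_config("stft", image_size = c(16, 16)),
                             mode = "image")
  expect_equal(dim(imgs$x), c(6, 16, 16, 3))
})
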