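test_that("WAV round trip preserves samples within quantization and metadata", {
  rec <- synthesize_recording("normal", 70, 2, 4000, seed = 2)
  p <- file.path(tempdir(), "rt.wav")
  write_wav(rec, p)
  back <- read_wav(p)
  expect_equal(back$sample_rate, 4000)
  expect_length(back$samples, length(rec$samples))
  expect_lte(max(abs(back$samples - rec$samples)), 2^-15)
})

test_that("reader rejects stereo and non-PCM files and missing paths", {
  # hand-build a 2-channel WAV header around 4 samples
  p <- file.path(tempdir(), "stereo.wav")
  con <- file(p, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L + 16L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(16L, con, size = 4, endian = "little")
  writeBin(integer(8), con, size = 2, endian = "little")
  close(con)
  expect_error(read_wav(p), class = "pcgnet_unsupported_format")
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), class = "pcgnet_io_error")

  # IEEE float format tag is refused
  pf <- file.path(tempdir(), "float.wav")
  raw <- readBin(p, "raw", file.size(p))
  raw[21] <- as.raw(3)  # format tag lives at offset 20 (0-based)
  writeBin(raw, pf)
  expect_error(read_wav(pf), class = "pcgnet_unsupported_format")
})

test_that("segmentation emits only full windows and inherits labels", {
  mk <- function(sec) pcg_recording(rep(0.1, sec * 1000), 1000, label = "abnormal",
                                    condition = "VSD")
  expect_length(segment_recording(mk(6), 6), 1)
  segs <- segment_recording(mk(13), 6)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$label, "abnormal")
  expect_length(segs[[1]]$samples, 6000)
  expect_length(segment_recording(mk(5), 6), 0)
  # overlap halves the stride
  expect_length(segment_recording(mk(12), 6, overlap_s = 3), 3)
  expect_error(segment_recording(mk(6), 6, overlap_s = 6),
               class = "pcgnet_invalid_parameter")
  # total emitted duration never exceeds the recording
  for (sec in c(6, 7, 11, 18)) {
    n <- length(segment_recording(mk(sec), 6))
    expect_lte(n * 6, sec)
  }
})

test_that("stratified split yields 48/6/6 with balanced classes on the study corpus", {
  manifest <- study_corpus()
  sp <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 11)
  counts <- table(sp$partition)
  expect_equal(as.integer(counts[c("train", "validation", "test")]),
               c(48L, 6L, 6L))
  by_class <- table(sp$partition, sp$label)
  expect_true(all(by_class[, "normal"] == by_class[, "abnormal"]))
  # disjoint + exhaustive
  expect_false(anyNA(sp$partition))
  # deterministic
  sp2 <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 11)
  expect_identical(sp$partition, sp2$partition)
  sp3 <- stratified_split(manifest, c(0.8, 0.1, 0.1), seed = 12)
  expect_false(identical(sp$partition, sp3$partition))
  expect_error(stratified_split(manifest, c(0.5, 0.5, 0.5)),
               class = "pcgnet_invalid_parameter")
})

test_that("split class proportions track the global ratio within one record", {
  set.seed(4)
  for (rep in 1:3) {
    n_ab <- sample(10:40, 1); n_no <- sample(10:40, 1)
    m <- data.frame(path = as.character(seq_len(n_ab + n_no)),
                    label = c(rep("abnormal", n_ab), rep("normal", n_no)))
    sp <- stratified_split(m, seed = rep)
    for (part in c("train", "validation", "test")) {
      sub <- sp[sp$partition == part, ]
      frac_global <- n_ab / (n_ab + n_no)
      expected <- frac_global * nrow(sub)
      expect_lte(abs(sum(sub$label == "abnormal") - expected), 1)
    }
  }
})

test_that("balanced resampling draws exact class counts without duplicates", {
  pool <- data.frame(path = as.character(1:500),
                     label = rep(c("normal", "abnormal"), 250))
  draws <- balanced_resample(pool, n_per_class = 218, iterations = 3, seed = 5)
  expect_length(draws, 3)
  for (d in draws) {
    expect_equal(nrow(d), 436)
    expect_equal(unname(class_counts(d)), c(218, 218))
    expect_false(anyDuplicated(d$path) > 0)
  }
  # determinism + iteration independence
  draws2 <- balanced_resample(pool, n_per_class = 218, iterations = 3, seed = 5)
  expect_identical(draws[[2]]$path, draws2[[2]]$path)
  expect_false(identical(sort(draws[[1]]$path), sort(draws[[2]]$path)))

  tiny <- data.frame(path = as.character(1:6), label = rep(c("normal", "abnormal"), 3))
  one <- balanced_resample(tiny, n_per_class = 2, iterations = 1, seed = 1)
  expect_equal(unname(class_counts(one[[1]])), c(2, 2))
  err <- tryCatch(balanced_resample(tiny, n_per_class = 10, iterations = 1, seed = 1),
                  error = identity)
  expect_s3_class(err, "pcgnet_capacity_error")
  expect_match(conditionMessage(err), "normal|abnormal")
})

test_that("manifest validation enforces unique paths and two-class labels", {
  expect_error(as_manifest(data.frame(path = c("a", "a"), label = c("normal", "normal"))),
               class = "pcgnet_invalid_parameter")
  expect_error(as_manifest(data.frame(path = c("a", "b"), label = c("normal", "murmur"))),
               class = "pcgnet_invalid_parameter")
  m <- as_manifest(data.frame(path = c("a", "b"), label = c("normal", "abnormal")))
  expect_s3_class(m, "dataset_manifest")
})
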