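test_that("confusion counts follow the patient-positive convention", {
  lab <- c(rep("abnormal", 3), rep("normal", 3))
  cm <- confusion(lab, lab)
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]), c(TP = 3L, FN = 0L, FP = 0L, TN = 3L))
  cm2 <- confusion(c("abnormal", "abnormal", "normal", "normal"),
                   rep("normal", 4))
  expect_equal(unlist(cm2[c("TP", "FN", "FP", "TN")]), c(TP = 0L, FN = 2L, FP = 0L, TN = 2L))
  expect_error(confusion(character(0), character(0)), class = "pcgnet_invalid_parameter")
  expect_error(confusion(c("abnormal"), c("abnormal", "normal")),
               class = "pcgnet_invalid_parameter")
  expect_error(confusion(c("abnormal"), c("murmur")), class = "pcgnet_invalid_parameter")
})

test_that("metric formulas and undefined markers behave", {
  m <- compute_metrics(structure(list(TP = 5, FN = 5, FP = 5, TN = 5),
                                 class = "confusion_matrix"))
  expect_equal(c(m$Acc, m$Se, m$Sp, m$MAcc), rep(0.5, 4))
  # no positives in the fold: sensitivity undefined, not NaN
  m2 <- compute_metrics(structure(list(TP = 0, FN = 0, FP = 1, TN = 4),
                                  class = "confusion_matrix"))
  expect_true(is.na(m2$Se))
  expect_true(is.na(m2$MAcc))
  expect_false(is.nan(m2$Se))
  expect_error(compute_metrics(structure(list(TP = 0, FN = 0, FP = 0, TN = 0),
                                         class = "confusion_matrix")),
               class = "pcgnet_invalid_parameter")
})

test_that("metrics agree with a brute-force recount on random label sets", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    lab <- sample(c("abnormal", "normal"), n, replace = TRUE)
    pred <- sample(c("abnormal", "normal"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    m <- compute_metrics(confusion(lab, pred))
    # recount from scratch with simple sums
    acc <- mean(lab == pred)
    se <- sum(lab == "abnormal" & pred == "abnormal") / sum(lab == "abnormal")
    sp <- sum(lab == "normal" & pred == "normal") / sum(lab == "normal")
    expect_equal(m$Acc, acc)
    expect_equal(m$Se, se)
    expect_equal(m$Sp, sp)
    expect_equal(m$MAcc, (se + sp) / 2)
    # the modified-accuracy identity holds exactly
    expect_lt(abs(m$MAcc - (m$Sp + m$Se) / 2), 1e-12)
  }
})

test_that("per-class precision and F1 match hand arithmetic", {
  perfect <- c(rep("abnormal", 3), rep("normal", 3))
  pf <- precision_f1(perfect, perfect)
  expect_equal(pf$precision, c(1, 1))
  expect_equal(pf$f1, c(1, 1))
  # TP=4, FP=1, FN=2 for the abnormal class:
  lab <- c(rep("abnormal", 6), rep("normal", 4))
  pred <- c(rep("abnormal", 4), "normal", "normal", "abnormal", rep("normal", 3))
  pf2 <- precision_f1(lab, pred)
  expect_equal(pf2$precision[pf2$class == "Ab"], 0.8)
  expect_equal(pf2$recall[pf2$class == "Ab"], 2 / 3, tolerance = 1e-4)
  expect_equal(pf2$f1[pf2$class == "Ab"], 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3),
               tolerance = 1e-6)
  expect_equal(round(pf2$f1[pf2$class == "Ab"], 4), 0.7273)
  # predictor that never says abnormal: precision undefined
  pf3 <- precision_f1(lab, rep("normal", 10))
  expect_true(is.na(pf3$precision[pf3$class == "Ab"]))
})

test_that("k-fold folds partition the data with near-equal stratified sizes", {
  y <- rep(c("abnormal", "normal"), each = 10)
  folds <- pcgnet:::stratified_folds(y, 10, seed = 2)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 2))
  for (f in 1:10) expect_equal(sum(y[folds == f] == "abnormal"), 1)
  # sizes differ by at most one in the uneven case
  y2 <- c(rep("abnormal", 13), rep("normal", 17))
  folds2 <- pcgnet:::stratified_folds(y2, 4, seed = 3)
  expect_lte(diff(range(table(folds2))), 2)  # at most one per class
  expect_identical(pcgnet:::stratified_folds(y, 5, seed = 9),
                   pcgnet:::stratified_folds(y, 5, seed = 9))
  expect_error(pcgnet:::stratified_folds(y, 21, seed = 1),
               class = "pcgnet_invalid_parameter")
})

test_that("cross-validation tests every example exactly once and reports fold metrics", {
  d <- toy_images(n_per_class = 10, size = 12)
  cv <- kfold_cv(d$x, d$y, toy_conv_builder(epochs = 20), k = 5, seed = 6)
  expect_length(cv$fold_metrics, 5)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), 20)
  total_tested <- sum(vapply(cv$fold_metrics, `[[`, numeric(1), "n"))
  expect_equal(total_tested, 20)
  expect_true(all(c("Acc", "Se", "Sp", "MAcc") %in% names(cv$summary$mean)))
  # separable data: well above chance
  expect_gt(cv$summary$mean[["Acc"]], 0.7)
})

test_that("the repeated balanced protocol aggregates iteration summaries", {
  d <- toy_images(n_per_class = 10, size = 12)
  rep2 <- repeated_protocol(d$x, d$y, toy_dense_builder(epochs = 3),
                            n_per_class = 5, iterations = 2, k = 2, seed = 4)
  expect_equal(nrow(rep2$iteration_summaries), 2)
  expect_equal(rep2$n_per_class, 5)
  expect_true(all(is.finite(rep2$grand$mean)))
})

test_that("null data (no murmur) stays at chance accuracy under the protocol", {
  d <- toy_images(n_per_class = 10, size = 12, murmur_gain = 0, seed = 33)
  rep0 <- repeated_protocol(d$x, d$y, toy_dense_builder(epochs = 4),
                            n_per_class = 8, iterations = 6, k = 4, seed = 8)
  # 6 iterations x 16 held-out examples; 3 sigma of a fair coin over ~96
  # (correlated) draws is well inside 0.20
  expect_lt(abs(rep0$grand$mean[["Acc"]] - 0.5), 0.2)
})

test_that("extractor comparison pairs splits and reports the full schema", {
  manifest <- study_corpus()[c(1:10, 31:40), ]
  class(manifest) <- c("dataset_manifest", "data.frame")
  tab <- compare_extractors(manifest, c("stft", "stft"),
                            model_builder = toy_dense_builder(epochs = 3),
                            image_size = c(12, 12), seed = 3)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("extractor", "precision_Ab", "precision_N", "f1_Ab", "f1_N",
                    "test_accuracy") %in% names(tab)))
  # identical extractor + identical seed -> identical rows (pairing control)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  expect_error(compare_extractors(manifest, character(0), toy_dense_builder()),
               class = "pcgnet_invalid_parameter")
})

test_that("cost report mirrors closed-form counts and sorts by size", {
  specs <- list(build_model1(c(50, 13)), build_model2(), build_model3())
  tab <- cost_report(specs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$parameters, sort(vapply(specs, count_parameters, numeric(1)),
                                    decreasing = TRUE))
  expect_equal(tab$model[1], "model2")   # the image CNN is the largest
  for (i in 1:3) {
    j <- which(tab$model == specs[[i]]$name)
    expect_equal(tab$parameters[j], count_parameters(specs[[i]]))
    expect_equal(tab$epochs[j], specs[[i]]$config$epochs)
  }
})
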