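test_that("confusion metrics follow the published formulas", {
  cm <- confusion_matrix(TP = 366, FN = 24, FP = 6, TN = 228)
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, 594 / 624, tolerance = 1e-12)
  expect_equal(m$precision, 366 / 372, tolerance = 1e-12)
  expect_equal(m$recall, 366 / 390, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (366 / 372) * (366 / 390) / (366 / 372 + 366 / 390),
               tolerance = 1e-12)
  expect_equal(m$specificity, 228 / 234, tolerance = 1e-12)
  # a perfect classifier scores one everywhere
  mp <- metrics_from_confusion(confusion_matrix(TP = 390, FN = 0, FP = 0, TN = 234))
  expect_equal(unlist(mp[c("accuracy", "precision", "recall", "f1", "specificity")]),
               setNames(rep(1, 5), c("accuracy", "precision", "recall", "f1",
                                     "specificity")))
  # degenerate denominators are undefined, not zero
  md <- metrics_from_confusion(confusion_matrix(TP = 0, FN = 5, FP = 0, TN = 3))
  expect_true(is.na(md$precision))
  expect_equal(md$recall, 0)
  expect_true(is.na(md$f1))
})

test_that("metrics agree with per-sample brute-force counting", {
  set.seed(30)
  for (k in 1:10) {
    n <- 50
    actual <- sample(c("normal", "pneumonia"), n, replace = TRUE)
    pred <- sample(c("normal", "pneumonia"), n, replace = TRUE)
    cm <- confusion_from_labels(pred, actual)
    expect_equal(cm$TP, sum(pred == "pneumonia" & actual == "pneumonia"))
    expect_equal(cm$TP + cm$FN, sum(actual == "pneumonia"))
    expect_equal(cm$FP + cm$TN, sum(actual == "normal"))
    m <- metrics_from_confusion(cm)
    if (!is.na(m$accuracy)) expect_equal(m$accuracy, mean(pred == actual))
    # F1 algebraic identity 2TP / (2TP + FP + FN)
    if (!is.na(m$f1)) {
      expect_equal(m$f1, 2 * cm$TP / (2 * cm$TP + cm$FP + cm$FN),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-based AUC equals the pairwise brute force", {
  expect_equal(auc_from_scores(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc_from_scores(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(auc_from_scores(0.5, 0.5), 0.5)   # all ties
  set.seed(31)
  for (k in 1:10) {
    pos <- round(runif(sample(3:12, 1)), 2)  # rounding forces some ties
    neg <- round(runif(sample(3:12, 1)), 2)
    expect_equal(auc_from_scores(pos, neg), ref_auc(pos, neg), tolerance = 1e-12)
  }
  expect_error(auc_from_scores(numeric(0), 1), "at least one")
})

test_that("stratified folds balance classes and partition the manifest", {
  fx <- small_dataset(image_size = 16, n_train = 25, n_val = 2, n_test = 2,
                      seed = 13)
  man <- subset_manifest(fx$manifest, "train")   # 25 + 25
  folds <- stratified_kfold(man, k = 5, seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_equal(unname(class_counts(f$val)), c(5L, 5L))
    expect_equal(nrow(f$train) + nrow(f$val), nrow(man))
    expect_length(intersect(f$train$path, f$val$path), 0L)
  }
  all_val <- sort(unlist(lapply(folds, function(f) f$val$path)))
  expect_identical(all_val, sort(man$path))      # union = input, no duplicates
  # determinism
  folds2 <- stratified_kfold(man, k = 5, seed = 1)
  expect_identical(folds[[3]]$val$path, folds2[[3]]$val$path)
  tiny <- man[c(1:6, 26:28), ]  # 6 normal, 3 pneumonia
  class(tiny) <- c("pn_manifest", "data.frame")
  expect_error(stratified_kfold(tiny, k = 5, seed = 1), "at least k")
})

test_that("per-class fold sizes are within one of each other", {
  fx <- small_dataset(image_size = 16, n_train = 25, n_val = 2, n_test = 2,
                      seed = 13)
  man <- subset_manifest(fx$manifest, "train")
  ragged <- man[c(1:23, 26:43), ]  # 23 normal, 18 pneumonia
  class(ragged) <- c("pn_manifest", "data.frame")
  folds <- stratified_kfold(ragged, k = 5, seed = 3)
  for (lbl in c("normal", "pneumonia")) {
    sizes <- vapply(folds, function(f) sum(f$val$label == lbl), integer(1))
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("the printed test metrics pin down a unique confusion matrix", {
  cm <- recover_confusion(390, 234, c(accuracy = 95.19, recall = 93.84))
  expect_equal(unclass(cm)[c("TP", "FN", "FP", "TN")],
               list(TP = 366L, FN = 24L, FP = 6L, TN = 228L))
  # perfect printed metrics recover the perfect matrix
  cmp <- recover_confusion(390, 234, c(accuracy = 100.00, recall = 100.00))
  expect_equal(cmp$TP, 390L); expect_equal(cmp$TN, 234L)
  # truncation-interval arithmetic: printed recall 50.00 fixes TP = 195
  cm50 <- recover_confusion(390, 234, c(accuracy = 62.50, recall = 50.00))
  expect_equal(cm50$TP, 195L)
  expect_equal(cm50$TP + cm50$TN, as.integer(round(0.625 * 624)))
  # inconsistent printed values raise an error
  expect_error(recover_confusion(10, 10, c(accuracy = 95.19, recall = 93.84)),
               "no integer confusion matrix")
})

test_that("truncation (not rounding) is what matches the printed recall", {
  pct <- 366 / 390 * 100
  expect_equal(floor(pct * 100) / 100, 93.84)   # truncates to the printed value
  expect_equal(round(pct, 2), 93.85)            # rounding would disagree
})

test_that("evaluate_model produces a coherent report on a trained fit", {
  fx <- small_dataset(image_size = 16, n_train = 6, n_val = 2, n_test = 4,
                      seed = 21)
  tr <- subset_manifest(fx$manifest, "train")
  te <- subset_manifest(fx$manifest, "test")
  m <- assemble_model(backbones = c("tiny_test", "tiny_test"),
                      input_size = 16L, seed = 1)
  res <- train_model(m, tr, training_config(epochs = 1, seed = 1, batch_size = 4),
                     pre_cfg = preprocess_config(target_size = c(16, 16)))
  ev <- evaluate_model(res$model, te,
                       pre_cfg = preprocess_config(target_size = c(16, 16)))
  expect_s3_class(ev, "pn_metrics")
  tot <- ev$confusion$TP + ev$confusion$FN + ev$confusion$FP + ev$confusion$TN
  expect_equal(tot, nrow(te))
  expect_true(ev$auc >= 0 && ev$auc <= 1)
})
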