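#' Confusion matrix for the two-class problem
#'
#' The positive class is "pneumonia" throughout the package.
#'
#' @param TP,FN,FP,TN non-negative integer cell counts (true positive,
#'   false negative, false positive, true negative).
#' @return an object of class `pn_confusion`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  v <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(v < 0) || any(v != floor(v))) stopf("confusion cells must be non-negative integers")
  structure(as.list(setNames(as.integer(v), names(v))), class = "pn_confusion")
}

#' Confusion matrix from predicted and true labels
#' @param predicted,actual character vectors of class labels.
#' @param positive the positive class label.
#' @return a `pn_confusion`.
#' @export
confusion_from_labels <- function(predicted, actual, positive = "pneumonia") {
  stopifnot(length(predicted) == length(actual))
  confusion_matrix(
    TP = sum(predicted == positive & actual == positive),
    FN = sum(predicted != positive & actual == positive),
    FP = sum(predicted == positive & actual != positive),
    TN = sum(predicted != positive & actual != positive))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`,
#' recall (sensitivity) `TP/(TP+FN)`, F1 (harmonic mean of precision and
#' recall) and specificity `TN/(TN+FP)`.  A metric whose denominator is
#' zero is reported as `NA` (undefined), never silently as 0 -- tiny
#' cross-validation folds can produce empty denominators.
#'
#' @param cm a `pn_confusion`.
#' @return an object of class `pn_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f1`, `specificity` as fractions in `[0, 1]` (or
#'   `NA` when undefined).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "pn_confusion"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  acc <- ratio(cm$TP + cm$TN, tot)
  prec <- ratio(cm$TP, cm$TP + cm$FP)
  rec <- ratio(cm$TP, cm$TP + cm$FN)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  spec <- ratio(cm$TN, cm$TN + cm$FP)
  structure(list(accuracy = acc, precision = prec, recall = rec,
                 f1 = f1, specificity = spec, confusion = cm),
            class = "pn_metrics")
}

#' @export
print.pn_metrics <- function(x, digits = 4, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else formatC(v * 100, digits = digits - 2, format = "f")
  cat(sprintf("accuracy %s%%  precision %s%%  recall %s%%  f1 %s%%  specificity %s%%\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$recall),
              fmt(x$f1), fmt(x$specificity)))
  if (!is.null(x$auc)) cat(sprintf("AUC %.4f\n", x$auc))
  invisible(x)
}

#' Rank-based AUC from class-separated scores
#'
#' Computes `P(score_pos > score_neg) + 0.5 P(tie)`, which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param pos_scores scores of the positive-class (pneumonia) samples.
#' @param neg_scores scores of the negative-class samples.
#' @return AUC in `[0, 1]`.
#' @export
auc_from_scores <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0 || nn == 0) stopf("both classes need at least one score")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Stratified k-fold split of a manifest
#'
#' Shuffles within each class (seeded) and deals records round-robin into
#' `k` folds, so per-class counts across folds differ by at most one, the
#' folds are disjoint, and their union is the input manifest.
#'
#' @param manifest a `pn_manifest`.
#' @param k number of folds (default 5).
#' @param seed integer seed; the same seed reproduces the same folds.
#' @return list of `k` elements, each `list(train = , val = )` manifests.
#' @export
stratified_kfold <- function(manifest, k = 5L, seed = 1L) {
  labs <- unique(manifest$label)
  tab <- class_counts(manifest)
  if (any(tab < k)) {
    stopf("every class needs at least k = %d samples (smallest has %d)", k, min(tab))
  }
  fold_id <- integer(nrow(manifest))
  withr::with_seed(seed, {
    for (l in labs) {
      ix <- which(manifest$label == l)
      ix <- ix[sample.int(length(ix))]
      fold_id[ix] <- rep_len(seq_len(k), length(ix))
    }
  })
  lapply(seq_len(k), function(f) {
    val <- manifest[fold_id == f, , drop = FALSE]
    tr <- manifest[fold_id != f, , drop = FALSE]
    class(val) <- class(tr) <- c("pn_manifest", "data.frame")
    list(train = tr, val = val)
  })
}

trunc2 <- function(pct) floor(pct * 100 + 1e-9) / 100

#' Recover the integer confusion matrix behind printed test metrics
#'
#' Published results often print only percentage metrics.  Given the test
#' class sizes and the printed accuracy and recall (two-decimal
#' percentages, interpreted as truncations of the exact fractions), this
#' searches all `(TP, TN)` integer pairs exhaustively and returns the
#' matrix consistent with both.  Truncation (not rounding) is used:
#' e.g. 366/390 = 93.846...% prints as 93.84 only under truncation.
#'
#' @param n_pos,n_neg number of positive (pneumonia) / negative (normal)
#'   test samples.
#' @param printed list or named vector with elements `accuracy` and
#'   `recall`, as printed percentages (e.g. `c(accuracy = 95.19, recall =
#'   93.84)`).
#' @return the unique consistent `pn_confusion`.  If no matrix is
#'   consistent an inconsistency error is raised; if several are, an
#'   ambiguity error listing all solutions.
#' @export
recover_confusion <- function(n_pos, n_neg, printed) {
  acc_p <- printed[["accuracy"]]; rec_p <- printed[["recall"]]
  tp <- 0:n_pos
  tp <- tp[trunc2(tp / n_pos * 100) == rec_p]
  sols <- list()
  for (TP in tp) {
    tn <- 0:n_neg
    acc <- trunc2((TP + tn) / (n_pos + n_neg) * 100)
    for (TN in tn[acc == acc_p]) {
      sols[[length(sols) + 1L]] <-
        confusion_matrix(TP = TP, FN = n_pos - TP, FP = n_neg - TN, TN = TN)
    }
  }
  if (length(sols) == 0) {
    stopf("no integer confusion matrix is consistent with accuracy %.2f and recall %.2f for %d/%d",
          acc_p, rec_p, n_pos, n_neg)
  }
  if (length(sols) > 1) {
    desc <- paste(vapply(sols, function(s)
      sprintf("(TP=%d, FN=%d, FP=%d, TN=%d)", s$TP, s$FN, s$FP, s$TN),
      character(1)), collapse = "; ")
    stopf("ambiguous: %d matrices are consistent: %s", length(sols), desc)
  }
  sols[[1]]
}

#' Evaluate a trained model on a manifest
#'
#' Computes the confusion matrix (positive class "pneumonia"), the derived
#' metrics and the rank-based AUC of the pneumonia probability.
#'
#' @param model a `pn_model` or a fitted [pneumonet()] object.
#' @param manifest a `pn_manifest` to evaluate on.
#' @param pre_cfg optional [preprocess_config()].
#' @return a `pn_metrics` with an additional `auc` element.
#' @export
evaluate_model <- function(model, manifest, pre_cfg = NULL) {
  if (inherits(model, "pneumonet")) model <- model$model
  stopifnot(inherits(model, "pn_model"))
  pre_cfg <- pre_cfg %||%
    preprocess_config(target_size = c(model$input_size, model$input_size))
  x <- manifest_to_array(manifest, pre_cfg)
  probs <- model_predict(model, x)
  pred <- colnames(probs)[max.col(probs)]
  m <- metrics_from_confusion(confusion_from_labels(pred, manifest$label))
  pos <- manifest$label == "pneumonia"
  m$auc <- if (any(pos) && any(!pos)) {
    auc_from_scores(probs[pos, "pneumonia"], probs[!pos, "pneumonia"])
  } else NA_real_
  m
}
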