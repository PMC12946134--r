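# Test-set metrics: accuracy, precision, recall, F1 from the confusion
# counts, AUC by the rank-sum statistic, exact binomial CI for accuracy.

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param successes number of successes (0..n).
#' @param n number of trials.
#' @param level confidence level, default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95) {
  if (successes < 0 || successes > n) stopf("successes must be in [0, n]")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' AUC by the rank-sum (Mann-Whitney) statistic
#'
#' Tie-corrected via midranks; invariant to strictly monotone transforms
#' of the scores.
#'
#' @param scores predicted probabilities or any monotone risk score.
#' @param labels binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluation report from confusion counts
#'
#' @param tp,fn,fp,tn confusion counts.
#' @param auc optional AUC to attach.
#' @param level confidence level for the accuracy CI.
#' @param model_id,feature_set_id provenance strings.
#' @return an `eval_report`: confusion counts, accuracy, precision,
#'   recall, f1, auc, and the exact binomial `ci95` for accuracy.
#' @export
eval_report_from_confusion <- function(tp, fn, fp, tn, auc = NA_real_,
                                       level = 0.95, model_id = NA_character_,
                                       feature_set_id = NA_character_) {
  total <- tp + fn + fp + tn
  acc <- (tp + tn) / total
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  structure(list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
                 accuracy = acc, precision = prec, recall = rec, f1 = f1,
                 auc = auc, ci95 = binomial_ci(tp + tn, total, level),
                 model_id = model_id, feature_set_id = feature_set_id),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s / %s]\n",
              x$model_id %||% "?", x$feature_set_id %||% "?"))
  cat(sprintf("  TP=%d FN=%d FP=%d TN=%d\n", x$confusion["TP"],
              x$confusion["FN"], x$confusion["FP"], x$confusion["TN"]))
  cat(sprintf("  accuracy %.4f (95%% CI %.4f, %.4f)  precision %.4f  recall %.4f  F1 %.4f  AUC %s\n",
              x$accuracy, x$ci95["lower"], x$ci95["upper"], x$precision,
              x$recall, x$f1,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' Predicts class-1 probabilities, thresholds at 0.5, and reports the
#' confusion counts, the four confusion-derived metrics, the rank-sum
#' AUC, and the exact binomial accuracy CI.
#'
#' @param model a fitted model from [train_models()] (an element of the
#'   bundle), or any object with a supported predict method.
#' @param test a [cohort_table()] or data.frame of test features.
#' @param labels test labels (ignored for a `cohort_table`).
#' @param threshold classification threshold on the class-1 probability.
#' @return an `eval_report`.
#' @export
evaluate <- function(model, test, labels = NULL, threshold = 0.5) {
  if (inherits(test, "cohort_table")) {
    labels <- test$outcome; df <- test$data
  } else {
    df <- as.data.frame(test)
    if (is.null(labels)) stopf("labels are required")
  }
  if (nrow(df) == 0) stopf("empty test set")
  p <- predict_prob(model, df)
  yhat <- as.integer(p >= threshold)
  y <- as.integer(labels)
  eval_report_from_confusion(tp = sum(yhat == 1 & y == 1),
                             fn = sum(yhat == 0 & y == 1),
                             fp = sum(yhat == 1 & y == 0),
                             tn = sum(yhat == 0 & y == 0),
                             auc = auc_rank(p, y),
                             model_id = attr(model, "model_id") %||% class(model)[1])
}
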