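# Classifier evaluation: confusion matrix, sensitivity/specificity, predictive
# values, balanced accuracy, trapezoidal ROC AUC, and the class-weighted
# accuracy / recall / F1 convention used for the aggregated test-set table.

#' Build an evaluation report from confusion-matrix counts
#'
#' Zero-denominator rates are reported as `NA` (undefined), never 0. The
#' weighted variants are support-weighted averages of the per-class metrics;
#' weighted recall equals overall accuracy by construction.
#'
#' @param tn,fp,fn,tp confusion-matrix counts at the decision threshold
#'   (negative = no event).
#' @param auc optional ROC AUC to carry in the report.
#' @param threshold decision threshold the counts were taken at.
#' @return an object of class `evaluation_report`.
#' @export
report_from_confusion <- function(tn, fp, fn, tp, auc = NA_real_, threshold = 0.5) {
  n <- tn + fp + fn + tp
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  acc <- div(tp + tn, n)
  f1_pos <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  prec_neg <- div(tn, tn + fn)
  f1_neg <- if (!is.na(prec_neg) && !is.na(spec) && (prec_neg + spec) > 0) {
    2 * prec_neg * spec / (prec_neg + spec)
  } else NA_real_
  n_pos <- tp + fn; n_neg <- tn + fp
  wavg <- function(a, b) div(n_neg * a + n_pos * b, n)
  structure(list(
    tn = tn, fp = fp, fn = fn, tp = tp, n = n, threshold = threshold,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    balanced_accuracy = (sens + spec) / 2,
    accuracy = acc, auc = auc, f1 = f1_pos,
    weighted_accuracy = acc,
    weighted_recall = wavg(spec, sens),
    weighted_f1 = wavg(f1_neg, f1_pos)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> n=%d  CM[tn=%d fp=%d fn=%d tp=%d] @thr=%.2f\n",
              x$n, x$tn, x$fp, x$fn, x$tp, x$threshold))
  cat(sprintf("  balanced acc %.3f | acc %.3f | AUC %s | sens %.3f | spec %.3f | PPV %.3f | NPV %.3f\n",
              x$balanced_accuracy, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(balanced_accuracy = x$balanced_accuracy, npv = x$npv, ppv = x$ppv,
             auc = x$auc, sensitivity = x$sensitivity, specificity = x$specificity,
             accuracy = x$accuracy, f1 = x$f1,
             weighted_recall = x$weighted_recall, weighted_f1 = x$weighted_f1,
             tn = x$tn, fp = x$fp, fn = x$fn, tp = x$tp)
}

#' Trapezoidal ROC AUC over unique score thresholds
#'
#' @param scores numeric classifier scores (higher = more event-like).
#' @param labels 0/1 labels; both classes must be present.
#' @return area under the ROC curve.
#' @export
auc_trapezoid <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop_module("risk_model", "AUC undefined: test set contains a single class")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group ties: cumulative counts at each unique threshold
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(1 - y))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Evaluate a fitted model on a test feature matrix
#'
#' @param model a `gbt_model`.
#' @param test a `feature_matrix` containing both classes.
#' @param threshold decision threshold; default 0.5.
#' @return an `evaluation_report`.
#' @export
evaluate <- function(model, test, threshold = 0.5) {
  if (!nrow(test$X)) stop_module("risk_model", "empty test set")
  pr <- gbt_predict(model, test, threshold)
  y <- test$y
  report_from_confusion(
    tn = sum(pr$class == 0 & y == 0), fp = sum(pr$class == 1 & y == 0),
    fn = sum(pr$class == 0 & y == 1), tp = sum(pr$class == 1 & y == 1),
    auc = auc_trapezoid(pr$prob, y), threshold = threshold)
}

#' Stratified k-fold cross-validation with in-fold imbalance correction
#'
#' Folds are stratified by class; any imbalance correction (SMOTE or random
#' undersampling) is applied inside each training fold only, never to the
#' held-out validation fold. The mean row is the per-metric arithmetic mean
#' of the fold rows.
#'
#' @param fm a `feature_matrix` (typically the training partition).
#' @param n_folds number of folds; default 5.
#' @param imbalance_method one of `"none"`, `"smote"`, `"undersample"`.
#' @param seed integer seed for fold assignment and resampling.
#' @param n_estimators,learning_rate,max_depth GBT hyperparameters.
#' @param threshold decision threshold.
#' @param k_neighbors SMOTE neighbourhood size.
#' @return an object of class `cv_report`: data.frame `folds`, named vector
#'   `mean`, and the fold assignment.
#' @export
cross_validate <- function(fm, n_folds = 5, imbalance_method = c("none", "smote", "undersample"),
                           seed = 1, n_estimators = 100, learning_rate = 0.1,
                           max_depth = 3, threshold = 0.5, k_neighbors = 5) {
  imbalance_method <- match.arg(imbalance_method)
  if (n_folds < 2) stop_module("risk_model", "n_folds must be >= 2")
  fold <- stratified_folds(fm$y, n_folds, seed)
  rows <- list()
  for (k in seq_len(n_folds)) {
    tr <- fm_subset(fm, which(fold != k))
    va <- fm_subset(fm, which(fold == k))
    if (length(unique(va$y)) < 2 || length(unique(tr$y)) < 2) {
      stop_module("risk_model", "fold %d does not contain both classes", k)
    }
    tr_bal <- switch(imbalance_method,
                     none = tr,
                     smote = smote_oversample(tr, k_neighbors = k_neighbors, seed = seed + k),
                     undersample = random_undersample(tr, seed = seed + k))
    model <- gbt_fit(tr_bal, n_estimators = n_estimators,
                     learning_rate = learning_rate, max_depth = max_depth)
    rows[[k]] <- as.data.frame(evaluate(model, va, threshold))
  }
  folds_df <- cbind(fold = seq_len(n_folds), do.call(rbind, rows))
  metric_cols <- c("balanced_accuracy", "npv", "ppv", "auc", "sensitivity",
                   "specificity", "accuracy", "f1", "weighted_recall", "weighted_f1")
  mean_row <- colMeans(folds_df[, metric_cols, drop = FALSE])
  structure(list(folds = folds_df, mean = mean_row, fold_assignment = fold,
                 imbalance_method = imbalance_method, n_folds = n_folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold stratified CV, imbalance method '%s'\n",
              x$n_folds, x$imbalance_method))
  df <- x$folds[, c("fold", "balanced_accuracy", "npv", "ppv", "auc", "sensitivity", "specificity")]
  print(df, row.names = FALSE, digits = 3)
  cat("mean:", paste(sprintf("%s=%.3f", names(x$mean)[1:6], x$mean[1:6]), collapse = " "), "\n")
  invisible(x)
}
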