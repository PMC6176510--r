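#' Confusion counts for binary seizure predictions
#'
#' Seizure (label 1) is the positive class throughout.
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @return A `confusion_counts` object with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  stopifnot(all(labels %in% c(0, 1)), all(predictions %in% c(0, 1)))
  structure(list(tp = sum(labels == 1 & predictions == 1),
                 fp = sum(labels == 0 & predictions == 1),
                 tn = sum(labels == 0 & predictions == 0),
                 fn = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Classification metrics from confusion counts
#'
#' Sensitivity (recall), specificity, accuracy, precision, the G-mean
#' (geometric mean of sensitivity and specificity) and the F-measure (the
#' beta-weighted harmonic combination of precision and sensitivity).  A zero
#' denominator yields `NA` — an explicit undefined marker, never a silent
#' zero.
#'
#' @param counts A [confusion()] result.
#' @param beta F-measure weight (1 gives the F1 score).
#' @return A `metrics_report`: named list of the six metrics plus `beta`.
#' @export
classification_metrics <- function(counts, beta = 1) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  acc <- safe_ratio(tp + tn, tp + fp + tn + fn)
  prec <- safe_ratio(tp, tp + fp)
  g_mean <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  f_den <- beta^2 * prec + sens
  f_measure <- if (is.na(prec) || is.na(sens) || f_den == 0) NA_real_
               else (1 + beta^2) * prec * sens / f_den
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 precision = prec, g_mean = g_mean, f_measure = f_measure,
                 beta = beta),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.4f  specificity %.4f  accuracy %.4f\n",
                     "precision   %.4f  G-mean      %.4f  F-measure %.4f",
                     " (beta=%g)\n"),
              x$sensitivity, x$specificity, x$accuracy,
              x$precision, x$g_mean, x$f_measure, x$beta))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with midrank tie handling: the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.  Constant scores give 0.5.
#'
#' @param scores Continuous classifier outputs.
#' @param labels True 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' Sensitivity/1-specificity pairs over every distinct score threshold, for
#' plotting.
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `fpr`, `tpr`, sorted by increasing
#'   false-positive rate.
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  pts <- t(vapply(th, function(t) {
    pred <- as.integer(scores >= t)
    c(fpr = sum(pred == 1 & labels == 0) / n_neg,
      tpr = sum(pred == 1 & labels == 1) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}
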