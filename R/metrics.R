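# Evaluation metrics for imbalanced binary screening: rank AUC, PR-AUC
# (average precision), and threshold metrics at 0.5.

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from mid-ranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stopf("roc_auc needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function average precision: sum over distinct score thresholds of
#' (recall increment) x precision. The random baseline equals the
#' positive-class prevalence (0.176 at 13 positives out of 74).
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stopf("pr_auc needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- which(c(s[-length(s)] != s[-1], TRUE))  # last index per distinct threshold
  precision <- tp[last] / (tp[last] + fp[last])
  recall <- tp[last] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Scores at or above the threshold are called positive. When no positive
#' calls and no positive labels exist, F1 is undefined and returned as 0
#' with a warning.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold (default 0.5).
#' @return one-row tibble: `f1`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (2 * tp + fp + fn == 0) {
    warning("F1 undefined (no positive labels or calls); returning 0")
    f1 <- 0
  } else f1 <- 2 * tp / (2 * tp + fp + fn)
  tibble::tibble(f1 = f1,
                 balanced_accuracy = mean(c(sens, spec), na.rm = TRUE),
                 sensitivity = sens, specificity = spec)
}
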