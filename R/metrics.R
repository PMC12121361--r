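#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)` via average ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_binary(labels)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average-precision formulation:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over thresholds at the distinct score
#' values in decreasing order; no linear interpolation between points.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector with at least one positive.
#' @return scalar in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  check_binary(labels)
  npos <- sum(labels == 1)
  if (npos == 0) stop("AUPRC needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each distinct score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Accuracy and F1 score at a hard threshold
#'
#' Predictions are positive when `score > threshold`. F1 with a zero
#' denominator (no predicted and no actual positives counted) is 0 by
#' convention.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector.
#' @param threshold classification threshold; default `0.5`.
#' @return named numeric vector `c(accuracy, f1)`.
#' @export
accuracy_f1 <- function(scores, labels, threshold = 0.5) {
  check_binary(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  acc <- mean(pred == labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, f1 = f1)
}

#' The four classification metrics plus their average
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector with both classes present.
#' @param threshold threshold for accuracy/F1; default `0.5`.
#' @return named vector `c(auroc, auprc, accuracy, f1, overall)` where
#'   `overall` is the plain mean of the four.
#' @export
metric_set <- function(scores, labels, threshold = 0.5) {
  af <- accuracy_f1(scores, labels, threshold)
  m <- c(auroc = auroc(scores, labels), auprc = auprc(scores, labels),
         accuracy = unname(af["accuracy"]), f1 = unname(af["f1"]))
  c(m, overall = mean(m))
}

check_binary <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  invisible(labels)
}
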