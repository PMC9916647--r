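#' Area under the ROC curve (trapezoidal rule)
#'
#' AUC of a score against a binary label, computed by the trapezoidal rule
#' over the ROC curve with tied scores grouped into a single threshold step.
#' This is numerically identical to the Mann-Whitney pair statistic with ties
#' counted one half: the fraction of (case, control) pairs the score orders
#' correctly.
#'
#' @param scores Numeric score vector (higher = more case-like).
#' @param labels Binary 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.8, 0.1), c(1, 0, 1)) # 0.5
#' @export
auc <- function(scores, labels) {
  check_metric_args(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC needs both classes present in `labels`", call. = FALSE)
  }
  r <- rank(scores) # midranks: ties count 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (rectangular rule)
#'
#' Summarizes the precision-recall curve as
#' `sum_n (R_n - R_(n-1)) * P_n` over descending-score thresholds
#' (right-anchored rectangles), with tied scores grouped into a single step.
#'
#' @inheritParams auc
#' @return Average precision in `(0, 1]`.
#' @examples
#' average_precision(c(0.9, 0.8, 0.1), c(1, 0, 1)) # 0.8333...
#' @export
average_precision <- function(scores, labels) {
  check_metric_args(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0L) stop("average precision needs at least one positive label", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # threshold steps at the last index of each tied score block
  step <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(y)[step]
  n_pred <- step
  precision <- tp / n_pred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

check_metric_args <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain missing values", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  invisible(TRUE)
}
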