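#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with mid-ranks for ties, so a constant score
#' gives exactly 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) true labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Tie-aware ROC curve: one point per distinct score threshold, from (0,0)
#' to (1,1).
#'
#' @inheritParams auc_roc
#' @return data.frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie block
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  data.frame(fpr = c(0, fp / max(sum(labels == 0), 1)),
             tpr = c(0, tp / max(sum(labels == 1), 1)),
             threshold = c(Inf, s[keep]))
}

#' Precision-recall curve points
#'
#' Tie-aware precision-recall curve (one point per distinct threshold).
#'
#' @inheritParams auc_roc
#' @return data.frame with columns `recall`, `precision`, `threshold`.
#' @export
pr_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[keep]
  n_pred <- seq_along(y)[keep]
  data.frame(recall = tp / max(sum(labels == 1), 1),
             precision = tp / n_pred,
             threshold = s[keep])
}

#' Area under the precision-recall curve
#'
#' Average precision: the sum over threshold steps of precision times the
#' recall increment, tie-aware. For a constant score this equals the
#' positive-class prevalence.
#'
#' @inheritParams auc_roc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  pts <- pr_points(scores, labels)
  dr <- diff(c(0, pts$recall))
  sum(pts$precision * dr)
}
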