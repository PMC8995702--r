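# ROC analysis, Youden cutoff selection, and confusion-matrix metrics for a
# scalar score against binary pre/post labels. The positive class is the
# post-operative (inflamed) one, and `score >= cutoff` predicts positive.

coerce_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    u <- sort(unique(labels))
    if (setequal(u, c("post", "pre"))) return(as.integer(labels == "post"))
    if (setequal(u, c("0", "1"))) return(as.integer(labels == "1"))
    stop("value error: cannot interpret labels; use 0/1, logical, or pre/post",
         call. = FALSE)
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (all(labels %in% c(0, 1))) return(as.integer(labels))
  stop("value error: labels must be binary", call. = FALSE)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique score values (ties move the operating
#' point in both coordinates simultaneously) and integrates the curve by the
#' trapezoidal rule, which equals the rank (Mann-Whitney) statistic with
#' half-credit for ties.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (0/1, logical, or "pre"/"post" with "post"
#'   positive); same length as `scores`.
#' @return An object of class `roc_result`: `auc` and `points` (data.frame
#'   `threshold`, `fpr`, `tpr`, starting at (0, 0) and ending at (1, 1)).
#' @export
roc_curve <- function(scores, labels) {
  y <- coerce_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels must have equal length", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("value error: scores must be finite", call. = FALSE)
  P <- sum(y == 1L); N <- sum(y == 0L)
  if (P == 0L || N == 0L)
    stop("value error: both classes must be present", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; ys <- y[o]
  tp <- cumsum(ys); fp <- cumsum(1L - ys)
  last <- which(c(s[-1L] != s[-length(s)], TRUE))  # last index of each tie group
  pts <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / N),
                    tpr = c(0, tp[last] / P))
  n <- nrow(pts)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1L] + pts$tpr[-n]) / 2)
  structure(list(auc = auc, points = pts, n_pos = P, n_neg = N),
            class = "roc_result")
}

#' Youden-optimal cutoff
#'
#' Chooses the threshold maximizing Youden's J = sensitivity + specificity
#' - 1; ties are broken toward higher specificity.
#'
#' @param roc A [roc_curve()] result.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[which.min(pts$fpr[best])]
  list(cutoff = pts$threshold[best],
       sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best],
       youden_j = j[best])
}

#' Confusion-matrix metrics at a cutoff
#'
#' `score >= cutoff` predicts the positive (post-operative/inflamed) class.
#'
#' @param scores,labels As in [roc_curve()].
#' @param cutoff Score threshold.
#' @return List with `accuracy`, `sensitivity`, `specificity`, and the 2x2
#'   `table` (tp, fp, tn, fn).
#' @export
confusion_metrics <- function(scores, labels, cutoff) {
  y <- coerce_labels(labels)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("value error: both classes must be present", call. = FALSE)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  list(accuracy = (tp + tn) / length(y),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       table = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Full ROC analysis of a score
#'
#' Convenience wrapper: ROC curve + Youden cutoff + confusion metrics at
#' that cutoff.
#'
#' @param scores,labels As in [roc_curve()].
#' @return A `roc_result` with `cutoff`, `sensitivity`, `specificity`,
#'   `accuracy` fields filled in.
#' @export
roc_analysis <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  yc <- youden_cutoff(roc)
  cm <- confusion_metrics(scores, labels, yc$cutoff)
  roc$cutoff <- yc$cutoff
  roc$sensitivity <- yc$sensitivity
  roc$specificity <- yc$specificity
  roc$accuracy <- cm$accuracy
  roc
}
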