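#' ROC curve and AUROC
#'
#' Thresholds sweep the distinct score values in descending order (tied
#' scores are grouped, so ties enter the curve together); the area is
#' computed by the trapezoidal rule over (FPR, TPR), which equals the
#' Mann-Whitney pair statistic counting ties as one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels; both classes must be present.
#' @return a `curve_result`: list with `points` (data.frame `x` = FPR,
#'   `y` = TPR, from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels %in% c(1, "1", "IR", TRUE))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUROC", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  last_of_group <- c(ss[-length(ss)] != ss[-1], TRUE)
  tp <- cumsum(ys)[last_of_group]
  fp <- cumsum(1 - ys)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(x = fpr, y = tpr), auc = auc,
                 n_pos = n_pos, n_neg = n_neg, type = "roc"),
            class = "curve_result")
}

#' Precision-recall curve and AUPRC
#'
#' Same descending threshold sweep over distinct scores; the area uses the
#' step-wise (right-continuous) rule `sum((R_i - R_{i-1}) * P_i)` rather than
#' trapezoids, which would over-estimate PR area. With constant scores the
#' single threshold gives recall 1 at precision equal to the positive
#' prevalence, so the area equals the prevalence.
#'
#' @inheritParams roc_auc
#' @return a `curve_result` with `points` (`x` = recall, `y` = precision).
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels %in% c(1, "1", "IR", TRUE))
  n_pos <- sum(y == 1)
  if (n_pos == 0) stop("at least one positive required for AUPRC", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  last_of_group <- c(ss[-length(ss)] != ss[-1], TRUE)
  tp <- cumsum(ys)[last_of_group]
  pred_pos <- which(last_of_group)
  recall <- tp / n_pos
  precision <- tp / pred_pos
  auc <- sum(diff(c(0, recall)) * precision)
  structure(list(points = data.frame(x = recall, y = precision), auc = auc,
                 n_pos = n_pos, n_neg = sum(y == 0), type = "pr"),
            class = "curve_result")
}

#' @export
print.curve_result <- function(x, ...) {
  cat(sprintf("<%s curve: auc = %.4f (%d pos / %d neg, %d points)>\n",
              toupper(x$type), x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' AUROC/AUPRC summary for a scored set
#'
#' @inheritParams roc_auc
#' @return list `auroc`, `auprc`, `n_pos`, `n_neg`.
#' @export
score_summary <- function(scores, labels) {
  r <- roc_auc(scores, labels)
  p <- pr_auc(scores, labels)
  list(auroc = r$auc, auprc = p$auc, n_pos = r$n_pos, n_neg = r$n_neg)
}
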