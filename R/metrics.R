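#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Equal scores are handled with mean ranks, which is exactly the
#' half-credit tie correction of the Mann-Whitney statistic.
#'
#' @param scores numeric classifier scores (higher = more cancer-like)
#' @param y labels; positives identified by `positive`
#' @param positive the positive-class label (default "CA")
#' @return AUC in `[0, 1]`
#' @export
auc_mannwhitney <- function(scores, y, positive = "CA") {
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hanley-McNeil variance of an AUC estimate
auc_variance <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  max(v, 0)
}

#' ROC curve points
#'
#' @inheritParams auc_mannwhitney
#' @return data.frame of (fpr, tpr, threshold), non-decreasing in both
#'   coordinates, from (0,0) to (1,1)
#' @export
roc_points <- function(scores, y, positive = "CA") {
  pos <- y == positive
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied thresholds
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- cumsum(p) / sum(p)
  fpr <- cumsum(!p) / sum(!p)
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]),
             threshold = c(Inf, s[keep]))
}

#' Classification metrics from a confusion matrix
#'
#' @param tp,fn,fp,tn confusion-matrix cells (positives = cancer)
#' @return named list: sensitivity, specificity, ppv, npv, accuracy
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = tp / (tp + fp),
       npv = tn / (tn + fn),
       accuracy = (tp + tn) / (tp + fn + fp + tn))
}

#' Specificity at a sensitivity floor
#'
#' Finds the largest score threshold whose sensitivity is at least
#' `target_sensitivity` and reports the specificity there.
#'
#' @inheritParams auc_mannwhitney
#' @param target_sensitivity required sensitivity (default 0.95)
#' @return list with threshold, sensitivity, specificity
#' @export
specificity_at_sensitivity <- function(scores, y, target_sensitivity = 0.95,
                                       positive = "CA") {
  pos <- y == positive
  cand <- sort(unique(scores), decreasing = TRUE)
  for (thr in cand) {
    sens <- mean(scores[pos] >= thr)
    if (sens >= target_sensitivity) {
      return(list(threshold = thr, sensitivity = sens,
                  specificity = mean(scores[!pos] < thr)))
    }
  }
  list(threshold = -Inf, sensitivity = 1, specificity = 0)
}
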