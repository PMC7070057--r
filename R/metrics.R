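#' Confusion-matrix metrics at a decision threshold
#'
#' Computes accuracy, sensitivity (recall), specificity, precision and
#' the Matthews correlation coefficient from binary labels and scores
#' thresholded at `threshold` (score >= threshold predicts positive).
#' Any rate with an empty denominator is 0 by convention, as is the MCC
#' when its denominator vanishes.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length (probabilities or any
#'   scores).
#' @param threshold decision threshold (default 0.5).
#' @return named list with counts `TP`, `FP`, `TN`, `FN` and rates
#'   `accuracy`, `sensitivity`, `specificity`, `precision`, `mcc`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stop("empty input")
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  rate <- function(num, den) if (den == 0) 0 else num / den
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       accuracy = (tp + tn) / length(labels),
       sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       precision = rate(tp, tp + fp),
       mcc = mcc)
}

#' ROC and precision-recall curves
#'
#' Sweeps the decision threshold over the distinct score values (tied
#' scores move together), integrating the ROC curve by the trapezoidal
#' rule (equivalent to the pairwise-comparison statistic with ties
#' counted one half) and the precision-recall curve as step-wise average
#' precision (the precision at each recall increment, no interpolation).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, larger = more positive.
#' @return list with `auc`, `aupr`, and data frames `roc` (`fpr`, `tpr`)
#'   and `pr` (`recall`, `precision`) of curve points.
#' @export
roc_pr_curves <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L) stop("both classes must be present")
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  # group tied scores so a threshold never splits a tie
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(l, grp, sum)
  n_g <- tapply(rep(1, length(l)), grp, sum)
  tp <- cumsum(tp_g)
  fp <- cumsum(n_g - tp_g)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auc = unname(auc), aupr = unname(aupr),
       roc = data.frame(fpr = unname(fpr), tpr = unname(tpr)),
       pr = data.frame(recall = unname(recall), precision = unname(precision)))
}

#' Gaussian interaction-profile kernel similarity
#'
#' The classical local behavior-similarity baseline: each entity is
#' described by its 0/1 interaction profile against the other side of a
#' bipartite relation, and similarity is the RBF kernel
#' `K(i,j) = exp(-gamma * ||y_i - y_j||^2)` with the bandwidth normalized
#' by the mean squared profile norm, `gamma = gamma_scale /
#' mean(||y_i||^2)`.
#'
#' @param profiles 0/1 matrix, one interaction profile per row.
#' @param gamma_scale bandwidth scale (default 1).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
gip_kernel <- function(profiles, gamma_scale = 1) {
  profiles <- as.matrix(profiles)
  mean_norm <- mean(rowSums(profiles^2))
  if (mean_norm == 0) stop("all interaction profiles are zero")
  gamma <- gamma_scale / mean_norm
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  K
}
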