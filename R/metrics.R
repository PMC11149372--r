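# Performance metrics: threshold-free (AUROC, AUPR, Tjur's R2), Youden-
# threshold classification metrics (sensitivity, specificity, PPV, NPV), and
# prevalence-adjusted predictive values.

check_two_class <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counting one half (the Mann-Whitney convention);
#' computed from score ranks. Invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels 0/1 labels.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))   # 1
auroc <- function(scores, labels) {
  check_two_class(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step integration over the ranked scores (average-precision form): the sum
#' over case-recovering thresholds of precision times the recall increment.
#' Tied scores are handled by treating each distinct score as one threshold.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  check_two_class(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # keep only the last entry of each tied-score block
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  n1 <- sum(labels == 1)
  precision <- tp / (tp + fp)
  recall <- tp / n1
  sum(precision * diff(c(0, recall)))
}

#' Tjur's R2 (coefficient of discrimination)
#'
#' Mean predicted case probability among cases minus the mean among
#' controls; bounded in `[-1, 1]`.
#'
#' @param probabilities Predicted probabilities.
#' @param labels 0/1 labels.
#' @return Scalar in `[-1, 1]`.
#' @export
tjur_r2 <- function(probabilities, labels) {
  check_two_class(labels)
  mean(probabilities[labels == 1]) - mean(probabilities[labels == 0])
}

#' Youden-optimal classification threshold
#'
#' Scans the candidate set of observed scores; at each candidate `t` an
#' individual is called positive when its score is `>= t`. Returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1, taking
#' the lowest threshold on ties.
#'
#' @inheritParams auroc
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
youden_threshold <- function(scores, labels) {
  check_two_class(labels)
  cand <- sort(unique(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  j_at <- vapply(cand, function(t) {
    pos <- scores >= t
    sum(pos & labels == 1) / n1 + sum(!pos & labels == 0) / n0 - 1
  }, numeric(1))
  best <- which.max(j_at)   # which.max takes the first (lowest) on ties
  t <- cand[best]
  pos <- scores >= t
  list(threshold = t,
       sensitivity = sum(pos & labels == 1) / n1,
       specificity = sum(!pos & labels == 0) / n0,
       j = j_at[best])
}

#' Prevalence-adjusted predictive values
#'
#' Recomputes PPV and NPV from sensitivity and specificity at an external
#' disease prevalence:
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`,
#' `NPV = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#' An undefined value (zero denominator) is returned as `NaN`.
#'
#' @param sensitivity,specificity,prevalence Scalars in `[0, 1]`.
#' @return List with `ppv` and `npv`.
#' @export
#' @examples
#' adjusted_ppv_npv(0.8, 0.9, 0.103)
adjusted_ppv_npv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, specificity >= 0,
            specificity <= 1, prevalence >= 0, prevalence <= 1)
  ppv_den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  npv_den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  list(ppv = if (ppv_den == 0) NaN else sensitivity * prevalence / ppv_den,
       npv = if (npv_den == 0) NaN else
         specificity * (1 - prevalence) / npv_den)
}

#' Full metric report for one evaluation
#'
#' Computes AUROC, AUPR and Tjur's R2 on the evaluation scores, picks the
#' Youden threshold on `threshold_scores`/`threshold_labels` (by default a
#' separate validation split; pass the evaluation data itself for
#' exact-replication mode) and derives sensitivity, specificity, PPV and NPV
#' at that threshold, plus prevalence-adjusted PPV/NPV when a prevalence is
#' supplied.
#'
#' @param scores,labels Evaluation (test) scores and 0/1 labels.
#' @param threshold_scores,threshold_labels Data used to choose the
#'   threshold (default: the evaluation data).
#' @param prevalence Optional external disease prevalence.
#' @return List of class `metric_report`.
#' @export
metric_report <- function(scores, labels, threshold_scores = scores,
                          threshold_labels = labels, prevalence = NULL) {
  yt <- youden_threshold(threshold_scores, threshold_labels)
  pos <- scores >= yt$threshold
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  tn <- sum(!pos & labels == 0); fn <- sum(!pos & labels == 1)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  out <- list(auroc = auroc(scores, labels),
              aupr = aupr(scores, labels),
              tjur_r2 = tjur_r2(scores, labels),
              youden_threshold = yt$threshold,
              sensitivity = sens, specificity = spec,
              ppv = if (tp + fp == 0) NaN else tp / (tp + fp),
              npv = if (tn + fn == 0) NaN else tn / (tn + fn),
              prevalence = prevalence,
              adjusted_ppv = NA_real_, adjusted_npv = NA_real_)
  if (!is.null(prevalence)) {
    adj <- adjusted_ppv_npv(sens, spec, prevalence)
    out$adjusted_ppv <- adj$ppv
    out$adjusted_npv <- adj$npv
  }
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> AUROC ", round(x$auroc, 3), ", AUPR ",
      round(x$aupr, 3), ", Tjur R2 ", round(x$tjur_r2, 3), "\n", sep = "")
  cat("  threshold ", signif(x$youden_threshold, 3), ": sens ",
      round(x$sensitivity, 3), ", spec ", round(x$specificity, 3),
      ", PPV ", round(x$ppv, 3), ", NPV ", round(x$npv, 3), "\n", sep = "")
  invisible(x)
}
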