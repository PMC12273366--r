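#' ROC area under the curve (Mann-Whitney form)
#'
#' The fraction of (positive, negative) score pairs ordered correctly, with
#' ties counted 0.5 — computed via midranks, identical to the O(n^2)
#' pairwise count.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

confusion_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold          # ties go to positive
  list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
       fn = sum(!pred & labels == 1), tn = sum(!pred & labels == 0))
}

#' F1 score at a binarization threshold
#'
#' Standard F1 (harmonic mean of precision and recall) after calling
#' `score >= threshold` positive; 0 when nothing is predicted positive.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @param threshold Binarization threshold (default 0.5).
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_at(scores, as.integer(labels), threshold)
  if (cm$tp + cm$fp == 0 || cm$tp == 0) return(0)
  prec <- cm$tp / (cm$tp + cm$fp)
  rec <- cm$tp / (cm$tp + cm$fn)
  2 * prec * rec / (prec + rec)
}

#' Sensitivity at a fixed specificity
#'
#' Sweeps all decision thresholds and reports the sensitivity at the
#' smallest threshold whose specificity is at least `spec_target`
#' (0 if no threshold attains the target without excluding all positives).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @param spec_target Required specificity in (0, 1).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(scores, labels, spec_target) {
  labels <- as.integer(labels)
  if (spec_target <= 0 || spec_target >= 1)
    stop("spec_target must lie in (0, 1)")
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("both classes must be present")
  # candidate thresholds: each unique score plus one above the maximum
  thr <- sort(unique(scores))
  thr <- c(thr, max(thr) + 1)
  for (tv in thr) {
    cm <- confusion_at(scores, labels, tv)
    spec <- cm$tn / (cm$tn + cm$fp)
    if (spec >= spec_target)
      return(cm$tp / (cm$tp + cm$fn))
  }
  0
}

#' Decision-curve net benefit
#'
#' For each threshold probability `p_t`, patients with `score >= p_t` are
#' called positive and the net benefit is
#' `TP/n - (FP/n) * p_t / (1 - p_t)`. The treat-all reference is
#' `prevalence - (1 - prevalence) * p_t / (1 - p_t)` and treat-none is 0.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels (0/1).
#' @param thresholds Grid of threshold probabilities in (0, 1)
#'   (default `seq(0.01, 0.99, by = 0.01)`).
#' @return Data frame with `threshold`, `net_benefit`, `reference_all`,
#'   `reference_none`.
#' @export
net_benefit_curve <- function(scores, labels,
                              thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  n <- length(labels)
  prev <- mean(labels == 1)
  rows <- lapply(thresholds, function(pt) {
    cm <- confusion_at(scores, labels, pt)
    w <- pt / (1 - pt)
    data.frame(threshold = pt,
               net_benefit = cm$tp / n - (cm$fp / n) * w,
               reference_all = prev - (1 - prev) * w,
               reference_none = 0)
  })
  do.call(rbind, rows)
}

#' Summary evaluation report for a scored cohort
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1).
#' @param spec_grid Specificities for the sensitivity table
#'   (default 0.6, 0.7, 0.8, 0.9).
#' @param threshold F1 binarization threshold.
#' @return List with `auc`, `f1`, `sensitivity_at` (named vector) and
#'   `net_benefit` (data frame).
#' @export
evaluate_scores <- function(scores, labels,
                            spec_grid = c(0.6, 0.7, 0.8, 0.9),
                            threshold = 0.5) {
  sens <- vapply(spec_grid, function(s)
    sensitivity_at_specificity(scores, labels, s), 1)
  names(sens) <- sprintf("spec_%.1f", spec_grid)
  list(auc = roc_auc(scores, labels),
       f1 = f1_score(scores, labels, threshold),
       sensitivity_at = sens,
       net_benefit = net_benefit_curve(scores, labels))
}
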