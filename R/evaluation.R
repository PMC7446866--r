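#' Confusion counts at a probability threshold
#'
#' Dichotomizes predicted probabilities at `threshold` (inclusive: a score
#' exactly at the threshold is predicted positive) and cross-tabulates
#' against the labels.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Logical (or 0/1) vector of outcomes, aligned with
#'   `scores`.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row tibble of class `confusion_summary`: `tp`, `fp`, `tn`,
#'   `fn`, `threshold`.
#' @export
#' @examples
#' confusion_at_threshold(c(0.9, 0.7, 0.6, 0.4, 0.2), c(1, 1, 0, 0, 0))
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) abort("`scores` must be non-empty.")
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  stopifnot(!anyNA(scores), !anyNA(labels))
  pred <- scores >= threshold
  out <- tibble::tibble(
    tp = sum(pred & labels),
    fp = sum(pred & !labels),
    tn = sum(!pred & !labels),
    fn = sum(!pred & labels),
    threshold = threshold
  )
  class(out) <- c("confusion_summary", class(out))
  out
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("%s undefined (zero denominator); returning NA.", what))
    return(NA_real_)
  }
  num / den
}

#' Classification performance metrics under class imbalance
#'
#' Derives the standard confusion metrics plus the imbalance-robust
#' summaries: balanced accuracy (mean of sensitivity and specificity),
#' lift (PPV over outcome prevalence, the fold-improvement over selecting
#' at random), and the reciprocal of PPV (false positives incurred per
#' true positive found, plus one). Undefined metrics (zero denominator)
#' are returned as `NA` with a warning, never as silent zeros.
#'
#' @param confusion A [confusion_at_threshold()] result (or any list with
#'   `tp`, `fp`, `tn`, `fn`).
#' @param auc Rank-based AUC to carry into the report (optional).
#' @param prevalence Outcome prevalence used for the lift (optional).
#' @return One-row tibble of class `performance_report`: `auc`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `ppv`, `npv`,
#'   `lift`, `flagged_reciprocal_ppv`.
#' @export
compute_performance <- function(confusion, auc = NA_real_,
                                prevalence = NA_real_) {
  tp <- confusion$tp; fp <- confusion$fp
  tn <- confusion$tn; fn <- confusion$fn
  stopifnot(length(tp) == 1, tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  if (tp + fp + tn + fn == 0) abort("empty confusion summary.")
  sens <- safe_ratio(tp, tp + fn, "sensitivity")
  spec <- safe_ratio(tn, tn + fp, "specificity")
  ppv <- safe_ratio(tp, tp + fp, "PPV")
  npv <- safe_ratio(tn, tn + fn, "NPV")
  out <- tibble::tibble(
    auc = auc,
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = (sens + spec) / 2,
    ppv = ppv,
    npv = npv,
    lift = if (!is.na(prevalence) && prevalence > 0) ppv / prevalence else NA_real_,
    flagged_reciprocal_ppv = if (!is.na(ppv) && ppv > 0) 1 / ppv else NA_real_
  )
  class(out) <- c("performance_report", class(out))
  out
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the receiver operating curve computed from midranks: the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, with ties counting one half. Equivalent to exhaustive
#' pairwise comparison but O(n log n).
#'
#' @param scores Numeric vector of predicted probabilities or scores.
#' @param labels Logical (or 0/1) outcome vector.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' compute_auc(c(0.8, 0.5, 0.5, 0.2), c(1, 0, 1, 0))
compute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present to compute the AUC.")
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate risk scores against labels
#'
#' Convenience wrapper chaining [confusion_at_threshold()],
#' [compute_auc()] and [compute_performance()] for a validation
#' partition.
#'
#' @inheritParams confusion_at_threshold
#' @param prevalence Outcome prevalence for the lift; defaults to the
#'   label mean.
#' @return A `performance_report` tibble.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            prevalence = mean(as.logical(labels))) {
  conf <- confusion_at_threshold(scores, labels, threshold)
  compute_performance(conf, auc = compute_auc(scores, labels),
                      prevalence = prevalence)
}
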