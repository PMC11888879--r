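#' Confusion-table performance metrics
#'
#' The five threshold metrics computed from the counts of true positives
#' (tp), false positives (fp), true negatives (tn) and false negatives (fn):
#'
#' * accuracy = (tp + tn) / (tp + fp + fn + tn)
#' * sensitivity = tp / (tp + fn)
#' * specificity = tn / (tn + fp)
#' * precision = tp / (tp + fp)
#' * F-measure = 2 tp / (2 tp + fp + fn)
#'
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0; repetition averages later exclude undefined values.
#'
#' @param tp,fp,tn,fn Non-negative integer counts; their sum must be >= 1.
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f_measure`.
#' @export
#' @examples
#' confusion_metrics(tp = 40, fp = 10, tn = 45, fn = 5)
confusion_metrics <- function(tp, fp, tn, fn) {
  check_counts(tp, fp, tn, fn)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    accuracy = ratio(tp + tn, tp + fp + fn + tn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    f_measure = ratio(2 * tp, 2 * tp + fp + fn)
  )
}

#' Cohen's kappa from a confusion table
#'
#' Chance-corrected agreement between predicted and true labels:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed accuracy and
#' `p_e` the agreement expected from the row/column margins. Returns `NA`
#' when `p_e = 1` (degenerate margins).
#'
#' @inheritParams confusion_metrics
#' @return A number in \[-1, 1\], or `NA`.
#' @export
#' @examples
#' cohen_kappa(tp = 40, fp = 10, tn = 45, fn = 5) # 0.70
cohen_kappa <- function(tp, fp, tn, fn) {
  check_counts(tp, fp, tn, fn)
  n <- tp + fp + tn + fn
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

check_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers.", class = "rceife_parameter_error")
  }
  if (sum(counts) < 1) abort("empty confusion table.", class = "rceife_parameter_error")
  invisible(NULL)
}

#' Area under the ROC curve
#'
#' The Mann–Whitney form of the AUC: the probability that a randomly chosen
#' positive sample outscores a randomly chosen negative one, ties counted as
#' 1/2 — identical to the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric positive-class scores, one per sample.
#' @param labels Matching labels (`pos`/`neg`, both present).
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c("pos", "pos", "neg", "neg")) # 0.75
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels differ in length.", class = "rceife_parameter_error")
  }
  n_pos <- sum(labels == "pos")
  n_neg <- sum(labels == "neg")
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present for AUC.", class = "rceife_metric_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "pos"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' All reported metrics from predictions on held-out data
#'
#' Convenience wrapper building the full per-level metric set from predicted
#' classes and positive-class scores: the five confusion metrics, AUC and
#' Cohen's kappa.
#'
#' @param truth True labels (`pos`/`neg`).
#' @param estimate Predicted labels (`pos`/`neg`).
#' @param scores Positive-class scores for AUC.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f_measure`, `auc`, `kappa`.
#' @export
classification_metrics <- function(truth, estimate, scores) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  tp <- sum(truth == "pos" & estimate == "pos")
  fp <- sum(truth == "neg" & estimate == "pos")
  tn <- sum(truth == "neg" & estimate == "neg")
  fn <- sum(truth == "pos" & estimate == "neg")
  out <- confusion_metrics(tp, fp, tn, fn)
  out$auc <- roc_auc(scores, truth)
  out$kappa <- cohen_kappa(tp, fp, tn, fn)
  out
}
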