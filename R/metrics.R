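#' Confusion counts for binary predictions
#'
#' Tabulates true/false positives and negatives for 0/1 labels, the building
#' block for [mcc()], [accuracy_score()] and [f1_score()].
#'
#' @param truth integer vector of true labels in \{0,1\}.
#' @param pred integer vector of predicted labels in \{0,1\}, same length.
#' @return A list with integer fields `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred))
    stop_dc("truth and pred lengths differ")
  if (!all(truth %in% 0:1) || !all(pred %in% 0:1))
    stop_dc("truth and pred must be binary 0/1")
  list(tp = sum(truth == 1L & pred == 1L),
       fp = sum(truth == 0L & pred == 1L),
       tn = sum(truth == 0L & pred == 0L),
       fn = sum(truth == 1L & pred == 0L))
}

#' Matthews correlation coefficient
#'
#' MCC is the correlation between predicted and true binary labels and is the
#' primary evaluation metric throughout this package because it remains
#' informative under heavy class imbalance. When any factor of the
#' denominator is zero (e.g. the classifier predicts a single class) the
#' coefficient is undefined; this implementation returns 0 in that case, a
#' declared convention.
#'
#' @param counts a confusion-count list as returned by [confusion_counts()],
#'   or `NULL` when `truth`/`pred` are given.
#' @param truth,pred optional raw 0/1 label vectors used when `counts` is
#'   `NULL`.
#' @return MCC in \[-1, 1\].
#' @examples
#' mcc(list(tp = 10, fp = 0, tn = 10, fn = 0))  # 1
#' mcc(truth = c(1, 0, 1, 0), pred = c(1, 1, 0, 0))  # 0
#' @export
mcc <- function(counts = NULL, truth = NULL, pred = NULL) {
  if (is.null(counts)) counts <- confusion_counts(truth, pred)
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Classification accuracy
#' @inheritParams mcc
#' @return Accuracy in \[0, 1\].
#' @export
accuracy_score <- function(counts = NULL, truth = NULL, pred = NULL) {
  if (is.null(counts)) counts <- confusion_counts(truth, pred)
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop_dc("empty confusion table")
  (counts$tp + counts$tn) / n
}

#' F1 score of the positive class
#'
#' Harmonic mean of precision and recall for class 1. Returns 0 when the
#' positive class is never predicted and never present (0/0 convention).
#' @inheritParams mcc
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(counts = NULL, truth = NULL, pred = NULL) {
  if (is.null(counts)) counts <- confusion_counts(truth, pred)
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(0)
  2 * counts$tp / den
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' random positive sample scores above a random negative one, with ties
#' counted one half (midrank convention).
#'
#' @param truth 0/1 vector; both classes must be present.
#' @param scores numeric score vector, higher meaning more positive.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auc_score <- function(truth, scores) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores))
    stop_dc("truth and scores lengths differ")
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_dc("AUC requires both classes present in truth")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Compute the full metric set from truth, hard labels and a ranking score.
metric_row <- function(truth, pred, scores) {
  cc <- confusion_counts(truth, pred)
  data.frame(mcc = mcc(cc),
             auc = auc_score(truth, scores),
             accuracy = accuracy_score(cc),
             f1 = f1_score(cc))
}
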