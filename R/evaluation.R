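# Confusion-matrix metrics, rank-based AUC and the antibody-array
# confirmation rule.

#' Confusion counts
#'
#' @param TP,TN,FP,FN non-negative integer counts; at least one must be
#'   positive.
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) < 1) stop("all-zero confusion counts")
  structure(as.list(counts), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' SEN = TP/(TP+FN); SP = TN/(TN+FP); ACC = (TP+TN)/N;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)). If any factor
#' under the MCC root is zero, MCC is reported as 0 with `mcc_degenerate =
#' TRUE`. Values are kept at full precision; [format()] rounds to 2 decimals
#' for display.
#'
#' @param counts a [confusion_counts()] object.
#' @return `eval_report` list: `counts`, `SEN`, `SP`, `ACC`, `MCC`,
#'   `mcc_degenerate`.
#' @examples
#' confusion_metrics(confusion_counts(972, 2493, 134, 341))
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  sen <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  acc <- (TP + TN) / n
  factors <- c(TP + FN, TP + FP, TN + FP, TN + FN)
  degenerate <- any(factors == 0)
  mcc <- if (degenerate) 0 else (TP * TN - FP * FN) / sqrt(prod(factors))
  structure(list(counts = counts, SEN = sen, SP = sp, ACC = acc,
                 MCC = mcc, mcc_degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("TP %d  TN %d  FP %d  FN %d\n",
              x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  cat(sprintf("SEN %.2f  SP %.2f  ACC %.2f  MCC %.2f%s\n",
              x$SEN, x$SP, x$ACC, x$MCC,
              if (x$mcc_degenerate) " (degenerate)" else ""))
  if (!is.null(x$AUC)) cat(sprintf("AUC %.2f\n", x$AUC))
  invisible(x)
}

#' Confusion counts from predictions and truth
#'
#' @param predicted,truth label vectors accepted by the same encodings as
#'   [rank_features()] labels.
#' @return a [confusion_counts()] object.
#' @export
count_confusion <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  p <- as_class_labels(predicted)
  t <- as_class_labels(truth)
  confusion_counts(TP = sum(p == 1 & t == 1), TN = sum(p == -1 & t == -1),
                   FP = sum(p == 1 & t == -1), FN = sum(p == -1 & t == 1))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counting one half.
#'
#' @param scores numeric decision scores.
#' @param labels class labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, -1, -1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  labels <- as_class_labels(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == -1L)
  if (n_pos == 0L || n_neg == 0L) stop("roc_auc requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return data.frame with `threshold`, `fpr`, `tpr`, one row per distinct
#'   score plus the two endpoints, ordered by increasing FPR.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_class_labels(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(th, function(t) {
    pred <- ifelse(scores >= t, 1L, -1L)
    c(fpr = sum(pred == 1 & labels == -1) / sum(labels == -1),
      tpr = sum(pred == 1 & labels == 1) / sum(labels == 1))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Antibody-array presence call
#'
#' A signal is confirmed present when it is at least `fold` times the
#' background of the array (>= semantics, per the manufacturer-style rule).
#'
#' @param signal non-negative signal intensity (vectorized).
#' @param background positive background intensity.
#' @param fold fold cutoff, default 5.
#' @return logical vector of presence flags.
#' @examples
#' array_confirmation(c(5000, 4999), 1000)
#' @export
array_confirmation <- function(signal, background, fold = 5) {
  stopifnot(is.numeric(signal), all(signal >= 0), is.numeric(fold), fold > 0)
  if (!is.numeric(background) || any(background <= 0)) {
    stop("background must be positive")
  }
  signal >= fold * background
}
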