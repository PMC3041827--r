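# F-score feature ranking: ratio of squared between-class mean separation to
# the summed unbiased within-class variances, computed per feature value.

#' F-score of one feature
#'
#' `((mean+ - mean)^2 + (mean- - mean)^2) / (var+ + var-)` where `mean` is the
#' pooled mean over both classes and `var+`, `var-` are the unbiased
#' within-class sums `sum((x - mean_class)^2) / (n_class - 1)`. Larger is more
#' discriminative. A zero denominator yields 0 when the class means agree
#' (no signal) and `Inf` when they differ (perfect separation), so perfectly
#' separating features are never discarded.
#'
#' @param values_pos numeric values of the feature in the positive class
#'   (length >= 2).
#' @param values_neg numeric values in the negative class (length >= 2).
#' @return non-negative F-score (possibly `Inf`).
#' @examples
#' f_score(c(0, 2), c(1, 3))  # 0.125
#' @export
f_score <- function(values_pos, values_neg) {
  stopifnot(length(values_pos) >= 2L, length(values_neg) >= 2L,
            is.numeric(values_pos), is.numeric(values_neg))
  m_pos <- mean(values_pos)
  m_neg <- mean(values_neg)
  m_all <- mean(c(values_pos, values_neg))
  num <- (m_pos - m_all)^2 + (m_neg - m_all)^2
  den <- sum((values_pos - m_pos)^2) / (length(values_pos) - 1L) +
    sum((values_neg - m_neg)^2) / (length(values_neg) - 1L)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Rank all features by F-score
#'
#' @param matrix numeric proteins x features matrix.
#' @param labels vector of class labels, `+1` (positive) / `-1` (negative),
#'   one per row; each class needs >= 2 members.
#' @return data.frame (`f_score_report`): `index` (0-based registry index),
#'   `feature`, `f_score`, `rank` (1 = highest; ties broken by ascending
#'   index).
#' @export
rank_features <- function(matrix, labels) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(labels))
  labels <- as_class_labels(labels)
  if (sum(labels == 1L) < 2L || sum(labels == -1L) < 2L) {
    stop("each class needs at least 2 members to compute F-scores")
  }
  pos <- matrix[labels == 1L, , drop = FALSE]
  neg <- matrix[labels == -1L, , drop = FALSE]
  fs <- vapply(seq_len(ncol(matrix)),
               function(j) f_score(pos[, j], neg[, j]), 0)
  rk <- rank_descending_stable(fs)
  out <- data.frame(
    index = seq_len(ncol(matrix)) - 1L,
    feature = if (is.null(colnames(matrix))) paste0("f", seq_len(ncol(matrix)) - 1L)
              else colnames(matrix),
    f_score = fs, rank = rk, stringsAsFactors = FALSE)
  class(out) <- c("f_score_report", "data.frame")
  out
}

# descending rank with ties broken by position (registry index)
rank_descending_stable <- function(x) {
  ord <- order(-x, seq_along(x))
  rk <- integer(length(x))
  rk[ord] <- seq_along(x)
  rk
}

#' Select features at an F-score threshold
#'
#' Keeps features whose F-score is `>=` the threshold (features exactly at
#' the threshold are retained), in registry order.
#'
#' @param report output of [rank_features()].
#' @param threshold non-negative F-score threshold.
#' @return integer vector of selected 0-based feature indices.
#' @export
filter_by_threshold <- function(report, threshold) {
  stopifnot(inherits(report, "f_score_report"),
            is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  sel <- report$index[report$f_score >= threshold]
  if (length(sel) == 0L) {
    stop(sprintf(
      "no feature reaches F-score threshold %g (max observed %g); lower the threshold",
      threshold, max(report$f_score)))
  }
  sort(sel)
}

#' Write an F-score report as TSV
#'
#' @param report output of [rank_features()].
#' @param path output path.
#' @param threshold optional threshold used to fill the `selected` column.
#' @return `path`, invisibly.
#' @export
write_f_score_report <- function(report, path, threshold = 0) {
  df <- as.data.frame(report)
  df$selected <- as.integer(df$f_score >= threshold)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# accepts +1/-1, 0/1, TRUE/FALSE, "positive"/"negative"; returns +1/-1 integer
as_class_labels <- function(labels) {
  if (is.character(labels)) {
    ok <- labels %in% c("positive", "negative")
    if (!all(ok)) stop("character labels must be 'positive' or 'negative'")
    return(ifelse(labels == "positive", 1L, -1L))
  }
  if (is.logical(labels)) return(ifelse(labels, 1L, -1L))
  u <- sort(unique(as.integer(labels)))
  if (all(u %in% c(0L, 1L)) && length(u) > 0L) {
    return(ifelse(as.integer(labels) == 1L, 1L, -1L))
  }
  if (!all(u %in% c(-1L, 1L))) stop("labels must encode two classes as +1/-1, 0/1, logical or positive/negative")
  as.integer(labels)
}
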