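#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement,
#' \eqn{(RI - E[RI]) / (\max RI - E[RI])}, computed through the standard
#' contingency-table identity. Equals 1 for identical partitions up to
#' relabeling and is near 0 for random labelings.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 2).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2L) stop("need at least two items", call. = FALSE)
  tab <- table(labels_a, labels_b)
  if (nrow(tab) == 1L && ncol(tab) == 1L) {
    message("both partitions are a single cluster; ARI is 1 by convention")
    return(1)
  }
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions all-singletons
  (sum_ij - expected) / (max_index - expected)
}

#' Confusion-matrix classification metrics
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A list with `recall`, `precision`, `acc`, `f1`; any metric whose
#'   denominator is zero is `NA` (explicitly undefined, never silently 0).
#' @export
confusion_metrics <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- safe_div(TP, TP + FN)
  precision <- safe_div(TP, TP + FP)
  acc <- safe_div(TP + TN, TP + TN + FP + FN)
  f1 <- if (is.na(recall) || is.na(precision) || (recall + precision) == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(recall = recall, precision = precision, acc = acc, f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed through the rank (Mann-Whitney) identity, with ties receiving
#' half credit, so scores that carry no information give exactly 0.5.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC is undefined when one class is absent", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties get half credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
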