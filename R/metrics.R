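#' Weighted accuracy of a confusion matrix
#'
#' The unweighted mean of per-class recalls (diagonal over row sum), the
#' accuracy notion used to weight each tree's contribution in the MCFS
#' relative-importance score. Robust to class imbalance: each class
#' counts equally regardless of size. Classes with no true samples in the
#' evaluation set (all-zero rows) are excluded from the mean.
#'
#' @param confusion square numeric count matrix, rows = true class,
#'   columns = predicted class.
#' @return a value in \code{[0, 1]}.
#' @examples
#' weighted_accuracy(matrix(c(8, 5, 2, 5), 2))  # recalls 0.8, 0.5 -> 0.65
#' @export
weighted_accuracy <- function(confusion) {
  check_confusion(confusion)
  rs <- rowSums(confusion)
  keep <- rs > 0
  mean(diag(as.matrix(confusion))[keep] / rs[keep])
}

check_confusion <- function(confusion) {
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0) || any(!is.finite(confusion)))
    stop("confusion matrix must hold non-negative finite counts")
  if (sum(confusion) == 0)
    stop("confusion matrix has no observations")
  invisible(confusion)
}

#' Information gain of a node split (bits)
#'
#' \code{H(parent) - sum(|child|/|parent| * H(child))} with base-2
#' entropies, where the children partition the parent label multiset.
#'
#' @param parent_labels vector of class labels at the node.
#' @param child_partitions list of label vectors, one per child; their
#'   concatenation must be a permutation of \code{parent_labels}.
#' @return non-negative gain in bits.
#' @examples
#' information_gain(c(1, 1, 0, 0), list(c(1, 1), c(0, 0)))  # 1 bit
#' @export
information_gain <- function(parent_labels, child_partitions) {
  if (length(parent_labels) == 0) stop("empty parent node")
  stopifnot(is.list(child_partitions))
  all_children <- unlist(lapply(child_partitions, as.character))
  if (!identical(sort(all_children), sort(as.character(parent_labels))))
    stop("child partitions must exactly partition the parent labels")
  lv <- sort(unique(as.character(parent_labels)))
  h <- function(lab) {
    cnt <- table(factor(as.character(lab), levels = lv))
    entropy_bits(matrix(as.numeric(cnt), 1))
  }
  n <- length(parent_labels)
  h(parent_labels) - sum(vapply(child_partitions, function(ch)
    length(ch) / n * h(ch), 0))
}

#' Multiclass Matthews correlation coefficient (Gorodkin's R_K)
#'
#' \deqn{R_K = \frac{c\,s - \sum_k p_k t_k}{\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}}
#' with \eqn{c} the trace, \eqn{s} the total count, \eqn{t_k} the row
#' (true) sums and \eqn{p_k} the column (predicted) sums. Degenerate
#' margins (either factor of the denominator zero, e.g. every sample
#' predicted into one class) are defined as 0. Reduces exactly to the
#' binary Matthews correlation coefficient for 2x2 matrices.
#'
#' @param confusion square count matrix, rows = true class.
#' @return a value in \code{[-1, 1]}.
#' @export
multiclass_mcc <- function(confusion) {
  check_confusion(confusion)
  m <- as.matrix(confusion)
  s <- sum(m)
  c0 <- sum(diag(m))
  tk <- rowSums(m)
  pk <- colSums(m)
  num <- c0 * s - sum(pk * tk)
  d1 <- s^2 - sum(pk^2)
  d2 <- s^2 - sum(tk^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  num / sqrt(d1 * d2)
}

#' Per-class and overall accuracy of a confusion matrix
#'
#' @param confusion square count matrix, rows = true class; row/column
#'   names (if present) name the classes.
#' @return list with \code{per_class} (named numeric; \code{NA} for a
#'   class with no true samples) and \code{overall} (trace over total).
#' @export
accuracies <- function(confusion) {
  check_confusion(confusion)
  m <- as.matrix(confusion)
  rs <- rowSums(m)
  per <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  names(per) <- rownames(m) %||% paste0("class", seq_len(nrow(m)))
  list(per_class = per, overall = sum(diag(m)) / sum(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
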