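# Binary classification tree with the entropy (base-2) split criterion.
# This is the workhorse of the MCFS ranking stage (which needs per-node
# information gain and sample fractions) and of the random-forest
# classifier adapter (which adds per-node feature subsampling via mtry).
#
# Determinism: given identical inputs and RNG state, the grown tree is
# identical. Tie-breaks are fixed: among equal-gain splits the smallest
# feature index wins, then the smallest threshold; leaf predictions break
# count ties toward the first factor level.

entropy_bits <- function(counts) {
  # counts: matrix, rows = nodes, cols = classes; returns per-row entropy
  n <- rowSums(counts)
  p <- counts / ifelse(n > 0, n, 1)
  h <- p * log2(p)
  h[counts == 0] <- 0
  -rowSums(h)
}

# Best threshold for one feature at one node. Returns NULL when the
# feature is constant, else list(threshold, ig).
best_split_feature <- function(v, y_int, k_classes, h_parent) {
  n <- length(v)
  ord <- order(v, method = "radix")
  vs <- v[ord]
  ys <- y_int[ord]
  cuts <- which(diff(vs) > 0)
  if (length(cuts) == 0) return(NULL)
  ind <- matrix(0, n, k_classes)
  ind[cbind(seq_len(n), ys)] <- 1
  cum <- apply(ind, 2, cumsum)
  left <- cum[cuts, , drop = FALSE]
  total <- cum[n, ]
  right <- matrix(total, nrow = length(cuts), ncol = k_classes,
                  byrow = TRUE) - left
  nl <- cuts
  nr <- n - cuts
  ig <- h_parent - (nl / n) * entropy_bits(left) - (nr / n) * entropy_bits(right)
  best <- which.max(ig)          # first max -> smallest threshold on ties
  if (ig[best] <= 1e-12) return(NULL)
  list(threshold = (vs[cuts[best]] + vs[cuts[best] + 1]) / 2,
       ig = ig[best])
}

#' Grow an entropy-criterion binary classification tree
#'
#' @param x numeric matrix (samples x features).
#' @param y factor of length \code{nrow(x)}.
#' @param min_split minimum samples required to attempt a split.
#' @param max_depth maximum depth (root = depth 0); \code{Inf} = none.
#' @param mtry if non-NULL, the number of features sampled (without
#'   replacement, consuming the RNG) as split candidates at each node;
#'   NULL considers all features.
#' @return an object of class \code{"entropy_tree"}: a list with a
#'   \code{nodes} data frame (columns \code{id, feature, threshold, left,
#'   right, n, ig, pred}; \code{feature} is the column index in \code{x},
#'   NA for leaves) and the class \code{levels}. \code{n} is the number of
#'   training rows reaching the node (a bootstrap multiset counts
#'   repeats), \code{ig} the information gain (bits) of the node's split.
#' @keywords internal
#' @export
grow_tree <- function(x, y, min_split = 2L, max_depth = Inf, mtry = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.factor(y)
  y_int <- as.integer(y)
  k <- nlevels(y)
  p <- ncol(x)
  nodes <- list()
  n_nodes <- 0L
  build <- function(idx, depth) {
    n_nodes <<- n_nodes + 1L   # reserve the id before recursing
    id <- n_nodes
    n <- length(idx)
    cnt <- tabulate(y_int[idx], nbins = k)
    pred <- which.max(cnt)  # ties -> first level
    h_parent <- entropy_bits(matrix(cnt, 1))
    leaf <- function() {
      nodes[[id]] <<- list(id = id, feature = NA_integer_,
                           threshold = NA_real_, left = NA_integer_,
                           right = NA_integer_, n = n, ig = NA_real_,
                           pred = pred)
      id
    }
    if (n < min_split || depth >= max_depth || h_parent <= 0) return(leaf())
    cand <- if (is.null(mtry)) seq_len(p) else
      sort(sample.int(p, min(mtry, p)))
    best <- NULL
    best_j <- NA_integer_
    for (j in cand) {
      s <- best_split_feature(x[idx, j], y_int[idx], k, h_parent)
      if (!is.null(s) && (is.null(best) || s$ig > best$ig + 1e-12)) {
        best <- s
        best_j <- j
      }
    }
    if (is.null(best)) return(leaf())
    go_left <- x[idx, best_j] <= best$threshold
    left_id <- build(idx[go_left], depth + 1L)
    right_id <- build(idx[!go_left], depth + 1L)
    nodes[[id]] <<- list(id = id, feature = best_j,
                         threshold = best$threshold, left = left_id,
                         right = right_id, n = n, ig = best$ig, pred = pred)
    id
  }
  build(seq_along(y_int), 0L)
  df <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(id = nd$id, feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, n = nd$n, ig = nd$ig,
               pred = nd$pred)))
  structure(list(nodes = df, levels = levels(y)), class = "entropy_tree")
}

#' Predict classes with a grown tree
#'
#' @param object an \code{entropy_tree}.
#' @param newdata numeric matrix with the same feature columns the tree
#'   was grown on.
#' @param ... unused.
#' @return factor of predicted classes with the training levels.
#' @keywords internal
#' @export
predict.entropy_tree <- function(object, newdata, ...) {
  nd <- object$nodes
  n <- nrow(newdata)
  out <- integer(n)
  route <- function(idx, node_id) {
    row <- nd[node_id, ]
    if (is.na(row$feature)) {
      out[idx] <<- row$pred
      return(invisible(NULL))
    }
    go_left <- newdata[idx, row$feature] <= row$threshold
    if (any(go_left)) route(idx[go_left], row$left)
    if (any(!go_left)) route(idx[!go_left], row$right)
  }
  if (n > 0) route(seq_len(n), 1L)
  factor(object$levels[out], levels = object$levels)
}
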