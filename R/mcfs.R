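#' Parameters for Monte-Carlo feature selection
#'
#' MCFS grows one entropy decision tree for each combination of \code{t}
#' random feature subsets and \code{m} bootstrap sample sets (\code{m * t}
#' trees in total) and scores every feature f by its relative importance
#'
#' \deqn{RI_f = \sum_{\tau=1}^{m t} (wAcc)^u \, IG(n_f(\tau))
#'   \left(\frac{\mathrm{no.\,in}\ n_f(\tau)}{\mathrm{no.\,in}\ \tau}\right)^v}
#'
#' summing, over every node \eqn{n_f(\tau)} split on f in tree \eqn{\tau},
#' the node's information gain (bits) weighted by the fraction of the
#' tree's training samples reaching the node, the whole tree weighted by
#' its weighted accuracy wAcc (mean per-class recall) on the bootstrap
#' draw's out-of-bag samples.
#'
#' @param t number of random feature subsets (default 100; published
#'   MCFS analyses often use thousands — raise for production runs).
#' @param m bootstrap/tree repetitions per subset (default 5).
#' @param subset_size features drawn (without replacement) per subset;
#'   default \code{max(5, ceiling(0.05 * p))}, the "relatively small
#'   subset" convention of the original MCFS method.
#' @param u exponent on wAcc (default 1).
#' @param v exponent on the node sample fraction (default 1).
#' @param min_split minimum node size to attempt a split (default 2).
#' @param max_depth maximum tree depth (default unlimited).
#' @param seed integer master seed; subset sampling, bootstrap draws and
#'   redraws all derive from it, so the ranking is reproducible.
#' @return an object of class \code{"mcfs_params"}.
#' @export
mcfs_params <- function(t = 100L, m = 5L, subset_size = NULL, u = 1, v = 1,
                        min_split = 2L, max_depth = Inf, seed = 1L) {
  stopifnot(t >= 1, m >= 1, u > 0, v > 0, min_split >= 2)
  if (!is.null(subset_size)) stopifnot(subset_size >= 1)
  structure(list(t = as.integer(t), m = as.integer(m),
                 subset_size = subset_size, u = u, v = v,
                 min_split = as.integer(min_split), max_depth = max_depth,
                 seed = as.integer(seed)),
            class = "mcfs_params")
}

#' RI contribution of one tree to one feature
#'
#' Literal evaluation of one summand of the relative-importance formula:
#' \code{wAcc^u * sum(IG * node_fraction^v)} over the tree's nodes split
#' on the feature; 0 when the feature splits no node.
#'
#' @param tree_eval list with \code{wacc} (the tree's out-of-bag weighted
#'   accuracy) and \code{nodes}, a data frame with columns
#'   \code{feature}, \code{ig} (bits) and \code{node_fraction} (samples
#'   reaching the node over samples used to grow the tree).
#' @param feature the feature identifier to score.
#' @param u,v the weighting exponents.
#' @return a non-negative real.
#' @export
ri_contribution <- function(tree_eval, feature, u = 1, v = 1) {
  nd <- tree_eval$nodes
  sel <- which(nd$feature == feature)
  if (length(sel) == 0) return(0)
  tree_eval$wacc^u * sum(nd$ig[sel] * nd$node_fraction[sel]^v)
}

#' Rank probes by MCFS relative importance
#'
#' Runs the full Monte-Carlo feature-selection procedure on a labeled
#' dataset: for each of \code{t} feature subsets and \code{m} bootstrap
#' draws, grows an entropy tree on the bootstrap sample restricted to the
#' subset, evaluates its weighted accuracy on the out-of-bag samples, and
#' accumulates every feature's \code{\link{ri_contribution}}. A bootstrap
#' draw whose out-of-bag set is empty is redrawn. Features are returned
#' in decreasing RI order; RI ties are broken by ascending probe id so
#' output files are byte-stable.
#'
#' @param dataset a labeled \code{\link{methyl_dataset}} (>= 2 classes).
#' @param params an \code{\link{mcfs_params}} object.
#' @param keep_trees if TRUE, attach the per-tree evaluations (features,
#'   out-of-bag wAcc, and per split node the global feature, IG and node
#'   fraction) as \code{attr(, "trees")} — the raw material for checking
#'   the ranking against a literal evaluation of the RI formula.
#' @return an object of class \code{"mcfs_ranking"}: a data frame with
#'   columns \code{probe_id} and \code{ri} (non-increasing), with the
#'   parameters in \code{attr(, "params")}.
#' @export
mcfs_rank <- function(dataset, params = mcfs_params(), keep_trees = FALSE) {
  stopifnot(inherits(dataset, "methyl_dataset"), inherits(params, "mcfs_params"))
  y <- dataset_labels(dataset)
  if (is.null(y)) stop("dataset must be labeled")
  x <- unclass(dataset)
  attr(x, "labels") <- NULL
  n <- nrow(x)
  p <- ncol(x)
  ss <- params$subset_size %||% max(5L, ceiling(0.05 * p))
  ss <- min(ss, p)
  if (!is.null(params$subset_size) && params$subset_size > p)
    stop(sprintf("subset_size (%d) exceeds feature count (%d)",
                 params$subset_size, p))
  set.seed(params$seed)
  ri <- numeric(p)
  trees <- if (keep_trees) vector("list", params$t * params$m) else NULL
  n_redraw <- 0L
  tree_i <- 0L
  for (si in seq_len(params$t)) {
    subset <- sample.int(p, ss)
    for (mi in seq_len(params$m)) {
      repeat {
        boot <- sample.int(n, n, replace = TRUE)
        oob <- which(tabulate(boot, nbins = n) == 0L)
        if (length(oob) > 0) break
        n_redraw <- n_redraw + 1L
      }
      tr <- grow_tree(x[boot, subset, drop = FALSE], y[boot],
                      min_split = params$min_split,
                      max_depth = params$max_depth)
      pred <- predict(tr, x[oob, subset, drop = FALSE])
      cm <- table(factor(y[oob], levels = levels(y)),
                  factor(pred, levels = levels(y)))
      wacc <- weighted_accuracy(cm)
      internal <- tr$nodes[!is.na(tr$nodes$feature), , drop = FALSE]
      tree_i <- tree_i + 1L
      if (nrow(internal) > 0) {
        gf <- subset[internal$feature]
        contrib <- wacc^params$u * internal$ig *
          (internal$n / n)^params$v
        agg <- rowsum(contrib, group = gf)
        ri[as.integer(rownames(agg))] <- ri[as.integer(rownames(agg))] + agg[, 1]
      }
      if (keep_trees) {
        trees[[tree_i]] <- list(
          features = colnames(x)[subset],
          wacc = wacc,
          nodes = data.frame(
            feature = if (nrow(internal)) colnames(x)[subset[internal$feature]]
                      else character(0),
            ig = internal$ig,
            node_fraction = internal$n / n,
            stringsAsFactors = FALSE))
      }
    }
  }
  if (n_redraw > 0)
    message(sprintf("mcfs_rank: redrew %d bootstrap draw(s) with empty out-of-bag sets",
                    n_redraw))
  ids <- colnames(x)
  ord <- order(-ri, ids, method = "radix")
  out <- data.frame(probe_id = ids[ord], ri = ri[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mcfs_ranking", "data.frame")
  attr(out, "params") <- params
  if (keep_trees) attr(out, "trees") <- trees
  out
}

#' Keep only features with positive relative importance
#'
#' Features never chosen for a split in any tree end with RI = 0 and have
#' no discriminative signal under the ensemble; downstream incremental
#' selection runs on the positive-RI list only.
#'
#' @param ranked an \code{\link{mcfs_rank}} result.
#' @return the ranking restricted to rows with \code{ri > 0}, order and
#'   attributes preserved.
#' @export
filter_positive_ri <- function(ranked) {
  stopifnot(inherits(ranked, "mcfs_ranking"))
  out <- ranked[ranked$ri > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(ranked)
  attr(out, "params") <- attr(ranked, "params")
  out
}

#' @export
print.mcfs_ranking <- function(x, n = 10, ...) {
  cat(sprintf("mcfs_ranking: %d features, %d with RI > 0\n",
              nrow(x), sum(x$ri > 0)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' @export
plot.mcfs_ranking <- function(x, ...) {
  graphics::plot(seq_len(nrow(x)), x$ri, type = "l", log = "x",
                 xlab = "rank", ylab = "relative importance (RI)",
                 main = "MCFS feature ranking", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
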