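#' Map probes to the union of their annotated genes
#'
#' @param probes character vector of probe ids.
#' @param annotation a \code{\link{probe_annotation}}.
#' @return character vector (sorted, unique) of gene symbols; probes with
#'   no annotation — or absent from the annotation entirely — contribute
#'   nothing and are counted in a single warning.
#' @export
probes_to_genes <- function(probes, annotation) {
  stopifnot(inherits(annotation, "probe_annotation"))
  probes <- unique(as.character(probes))
  known <- probes %in% names(annotation)
  if (any(!known))
    warning(sprintf("%d probe(s) absent from the annotation (treated as unannotated)",
                    sum(!known)))
  sets <- annotation[probes[known]]
  n_empty <- sum(lengths(sets) == 0)
  if (n_empty > 0)
    message(sprintf("probes_to_genes: %d probe(s) map to no gene", n_empty))
  sort(unique(unlist(sets, use.names = FALSE)))
}

#' Hypergeometric over-representation p-value (upper tail)
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}: the chance of
#' seeing at least \code{k} term members among \code{n} genes drawn
#' without replacement from a universe of \code{N} genes of which
#' \code{K} belong to the term.
#'
#' @param k observed term members among the selected genes.
#' @param K term members in the universe.
#' @param n selected gene count.
#' @param N universe size.
#' @return p-value in (0, 1]; \code{k = 0} gives exactly 1.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n))
    stop(sprintf("invalid hypergeometric bounds: k=%d K=%d n=%d N=%d",
                 k, K, n, N))
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: with p-values sorted ascending,
#' \code{q_i = min_{j >= i} (p_j * M / j)} capped at 1, mapped back to
#' the input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted values in (0, 1], same order as the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values > 0), all(p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric term over-representation with BH-FDR
#'
#' Tests every term of the map for over-representation of the selected
#' genes against the universe. Term gene sets are intersected with the
#' universe before counting; terms with fewer than \code{min_term_size}
#' universe genes are excluded from the tested family (singleton terms
#' are mostly noise). The multiple-testing family is all tested terms of
#' this one call.
#'
#' @param selected_genes character vector of selected gene symbols; must
#'   be non-empty. Genes outside the universe are dropped with a warning.
#' @param universe_genes character vector, the gene universe (typically
#'   all genes mapped from every probe on the analyzed matrix).
#' @param terms a \code{\link{term_map}}.
#' @param fdr_threshold significance cut on the adjusted values
#'   (default 0.05).
#' @param min_term_size minimum universe genes per tested term
#'   (default 2).
#' @param keep_empty keep rows for tested terms with \code{k = 0}
#'   (default TRUE).
#' @return an object of class \code{"enrichment_table"}: a data frame
#'   with columns \code{term_id, name, k, K, n, N, p, fdr, significant},
#'   sorted by fdr, then p, then term id.
#' @export
enrich <- function(selected_genes, universe_genes, terms,
                   fdr_threshold = 0.05, min_term_size = 2L,
                   keep_empty = TRUE) {
  stopifnot(inherits(terms, "term_map"))
  universe <- unique(as.character(universe_genes))
  if (length(universe) == 0) stop("empty gene universe")
  selected <- unique(as.character(selected_genes))
  if (length(selected) == 0) stop("empty gene selection")
  outside <- setdiff(selected, universe)
  if (length(outside) > 0) {
    warning(sprintf("%d selected gene(s) outside the universe dropped",
                    length(outside)))
    selected <- intersect(selected, universe)
    if (length(selected) == 0) stop("no selected gene inside the universe")
  }
  N <- length(universe)
  n <- length(selected)
  tsets <- lapply(unclass(terms), intersect, universe)
  keep <- lengths(tsets) >= min_term_size
  tsets <- tsets[keep]
  if (length(tsets) == 0)
    stop("no term with enough universe genes to test")
  K <- lengths(tsets)
  k <- vapply(tsets, function(g) length(intersect(g, selected)), 0L)
  p <- vapply(seq_along(tsets), function(i)
    hypergeom_upper_tail(k[i], K[i], n, N), 0)
  fdr <- bh_fdr(p)
  nm <- attr(terms, "term_names")[names(tsets)]
  out <- data.frame(term_id = names(tsets), name = unname(nm),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p), fdr = fdr,
                    significant = fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  if (!keep_empty) out <- out[out$k > 0, , drop = FALSE]
  out <- out[order(out$fdr, out$p, out$term_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' @export
print.enrichment_table <- function(x, n = 10, ...) {
  cat(sprintf("enrichment_table: %d tested terms, %d significant at FDR < %g\n",
              nrow(x), sum(x$significant),
              attr(x, "fdr_threshold") %||% 0.05))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}
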