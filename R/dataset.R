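#' Construct a labeled methylation dataset
#'
#' The central container of the pipeline: a numeric matrix of beta values
#' (fraction methylated, each in \code{[0, 1]}) stored in the internal
#' \code{[sample, probe]} orientation, optionally with a per-sample class
#' label. All downstream stages (MCFS ranking, IFS, enrichment) consume
#' this type.
#'
#' @param values numeric matrix, samples as rows and probes as columns,
#'   with unique non-empty \code{rownames} (sample ids) and
#'   \code{colnames} (probe ids); every entry finite and in \code{[0, 1]}.
#' @param labels optional per-sample class labels: a factor or character
#'   vector, either unnamed of length \code{nrow(values)} or named by
#'   sample id. At least two classes with >= 1 sample each are required
#'   once labels are set.
#' @return an object of class \code{"methyl_dataset"}: the matrix with a
#'   \code{labels} attribute (a factor aligned to rows, or \code{NULL}).
#' @examples
#' m <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
#' d <- methyl_dataset(m, labels = c(s1 = "A", s2 = "B"))
#' n_samples(d)
#' @export
methyl_dataset <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix [sample, probe]")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample ids as rownames and probe ids as colnames")
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  check_ids(rownames(values), "sample")
  check_ids(colnames(values), "probe")
  bad <- which(!is.finite(values) | values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid beta value at probe '%s', sample '%s' (%s): must be finite and in [0,1]",
      colnames(values)[bad[1, 2]], rownames(values)[bad[1, 1]],
      format(values[bad[1, , drop = FALSE]])))
  }
  x <- structure(values, class = c("methyl_dataset", "matrix", "array"))
  if (!is.null(labels)) x <- attach_labels(x, labels) else attr(x, "labels") <- NULL
  x
}

check_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids)))
    stop(sprintf("empty or missing %s id", what))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("duplicate %s ids: %s", what,
                 paste(utils::head(unique(dup), 5), collapse = ", ")))
  invisible(ids)
}

#' Attach class labels to a dataset
#'
#' @param dataset a \code{\link{methyl_dataset}}.
#' @param labels factor or character; unnamed of length \code{n_samples}
#'   (taken in row order) or named by sample id. Label entries for sample
#'   ids absent from the dataset are ignored with a warning; a dataset
#'   sample missing from a named label vector is an error.
#' @return the dataset with a per-sample factor in \code{attr(, "labels")}.
#' @export
attach_labels <- function(dataset, labels) {
  stopifnot(inherits(dataset, "methyl_dataset"))
  sids <- rownames(dataset)
  lab <- as.character(labels)
  names(lab) <- if (!is.null(names(labels))) trimws(names(labels)) else NULL
  if (is.null(names(lab))) {
    if (length(lab) != length(sids))
      stop(sprintf("unnamed labels must have length %d (one per sample), got %d",
                   length(sids), length(lab)))
    names(lab) <- sids
  } else {
    extra <- setdiff(names(lab), sids)
    if (length(extra) > 0)
      warning(sprintf("ignoring labels for %d unknown sample(s): %s",
                      length(extra),
                      paste(utils::head(extra, 5), collapse = ", ")))
    missing <- setdiff(sids, names(lab))
    if (length(missing) > 0)
      stop(sprintf("no label for sample(s): %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    lab <- lab[sids]
  }
  if (anyNA(lab) || any(!nzchar(trimws(lab))))
    stop("labels must be non-empty strings")
  lab <- factor(trimws(lab))
  if (nlevels(lab) < 2)
    stop("at least 2 classes are required")
  attr(dataset, "labels") <- lab
  dataset
}

#' @rdname methyl_dataset
#' @export
n_samples <- function(dataset) nrow(dataset)

#' @rdname methyl_dataset
#' @export
n_probes <- function(dataset) ncol(dataset)

#' @rdname methyl_dataset
#' @param dataset a \code{methyl_dataset}.
#' @export
dataset_labels <- function(dataset) attr(dataset, "labels")

#' Restrict a dataset to a subset of probes (order preserved as given)
#'
#' @param dataset a \code{\link{methyl_dataset}}.
#' @param probe_ids character vector of probe ids, all present.
#' @return a \code{methyl_dataset} with the same samples and labels.
#' @export
subset_probes <- function(dataset, probe_ids) {
  missing <- setdiff(probe_ids, colnames(dataset))
  if (length(missing) > 0)
    stop(sprintf("probe(s) not in dataset: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))
  out <- dataset[, probe_ids, drop = FALSE]
  structure(out, class = class(dataset), labels = attr(dataset, "labels"))
}

#' Permute class labels uniformly at random (null model)
#'
#' Returns the same beta values with the label vector shuffled; class
#' counts are preserved. Used to build empirical null distributions for
#' recovery experiments.
#'
#' @param dataset a labeled \code{\link{methyl_dataset}}.
#' @param seed integer RNG seed.
#' @return a \code{methyl_dataset} with permuted labels.
#' @export
permute_labels <- function(dataset, seed) {
  lab <- dataset_labels(dataset)
  if (is.null(lab)) stop("dataset has no labels to permute")
  set.seed(as.integer(seed))
  perm <- sample(length(lab))
  newlab <- lab[perm]
  names(newlab) <- rownames(dataset)
  attr(dataset, "labels") <- newlab
  dataset
}

#' @export
print.methyl_dataset <- function(x, ...) {
  lab <- attr(x, "labels")
  cat(sprintf("methyl_dataset: %d samples x %d probes\n", nrow(x), ncol(x)))
  if (is.null(lab)) {
    cat("  labels: <unset>\n")
  } else {
    tab <- table(lab)
    cat(sprintf("  classes: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}
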