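#' Specification for a synthetic methylation world
#'
#' Describes a 450K-style beta-value dataset with a small planted set of
#' class-discriminative probes, plus matching probe-to-gene and
#' gene-to-term annotations in which exactly one term (the planted genes)
#' is genuinely enriched. Defaults mirror the motivating three-subtype
#' glioma study: unbalanced classes of 78/46/80 samples, 42,383 probes,
#' and a compact signature of 20 discriminative probes.
#'
#' Beta values are drawn from Beta distributions parameterized by
#' (mean, concentration): probe j has shape parameters
#' \code{(mu * s, (1 - mu) * s)}, which keeps values in (0, 1) with the
#' bounded, skewed spread typical of methylation arrays (s = 30 gives a
#' within-class sd of about 0.08 at mu = 0.5). A noise probe shares one
#' mean \code{mu ~ Uniform(0.2, 0.8)} across classes; an informative
#' probe gets class-specific means \code{mu, mu + delta, mu - delta}
#' (clipped to (0.05, 0.95)), with the class order randomized per probe
#' so no single class is uniformly hyper-methylated.
#'
#' @param n_per_class named integer vector, class label -> sample count.
#' @param n_probes total probe count.
#' @param n_informative number of planted discriminative probes
#'   (< \code{n_probes}).
#' @param effect separation delta in (0, 0.5]: difference in class mean
#'   beta on informative probes.
#' @param concentration Beta-distribution precision s > 0.
#' @param seed integer RNG seed (single source of all randomness).
#' @param frac_unannotated fraction of noise probes mapping to no gene
#'   (intergenic), default 0.25.
#' @param max_genes_per_probe maximum genes per annotated probe
#'   (default 2; multi-gene probes exercise the union semantics).
#' @param planted_term_size size of the planted term; default = the
#'   planted gene count, so enrichment recovery has a known optimum.
#'   Values above that are padded with filler genes.
#' @param n_filler_terms number of random filler terms (>= 20).
#' @param n_filler_genes size of the filler gene pool.
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_per_class = c(A = 78L, B = 46L, C = 80L),
                           n_probes = 42383L,
                           n_informative = 20L,
                           effect = 0.25,
                           concentration = 30,
                           seed = 1L,
                           frac_unannotated = 0.25,
                           max_genes_per_probe = 2L,
                           planted_term_size = NULL,
                           n_filler_terms = 30L,
                           n_filler_genes = NULL) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class))))
    stop("n_per_class must be a named vector (class label -> count)")
  stopifnot(length(n_per_class) >= 2, all(n_per_class >= 1),
            n_probes >= 1, n_informative >= 0,
            n_informative < n_probes,
            effect > 0, effect <= 0.5,
            concentration > 0,
            frac_unannotated >= 0, frac_unannotated < 1,
            max_genes_per_probe >= 1,
            n_filler_terms >= 20)
  if (is.null(n_filler_genes))
    n_filler_genes <- max(50L, as.integer(round(0.4 * n_probes)))
  if (!is.null(planted_term_size) && planted_term_size < n_informative)
    stop("planted_term_size cannot be smaller than n_informative")
  structure(list(n_per_class = stats::setNames(as.integer(n_per_class),
                                               names(n_per_class)),
                 n_probes = as.integer(n_probes),
                 n_informative = as.integer(n_informative),
                 effect = effect, concentration = concentration,
                 seed = as.integer(seed),
                 frac_unannotated = frac_unannotated,
                 max_genes_per_probe = as.integer(max_genes_per_probe),
                 planted_term_size = planted_term_size,
                 n_filler_terms = as.integer(n_filler_terms),
                 n_filler_genes = as.integer(n_filler_genes)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled dataset with planted signal
#'
#' Draws the beta-value matrix, the probe-to-gene annotation and the term
#' map described by a \code{\link{synthetic_spec}}, and returns them
#' together with the generator's ground truth (planted probe ids, the
#' per-class mean matrix, the planted term and its genes) for recovery
#' experiments. All randomness derives from \code{spec$seed}; the same
#' spec always yields identical output.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list of class \code{"synthetic_methylation"} with elements
#'   \code{dataset} (\code{\link{methyl_dataset}}, labeled),
#'   \code{annotation} (\code{\link{probe_annotation}}),
#'   \code{terms} (\code{\link{term_map}}) and \code{truth} (list:
#'   \code{informative_probe_ids}, \code{class_means},
#'   \code{planted_term_id}, \code{planted_genes}).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- length(spec$n_per_class)
  classes <- names(spec$n_per_class)
  n <- sum(spec$n_per_class)
  p <- spec$n_probes
  s <- spec$concentration
  delta <- spec$effect

  sample_ids <- sprintf("S%04d", seq_len(n))
  probe_ids <- sprintf("cg%08d", seq_len(p))
  labels <- factor(rep(classes, times = spec$n_per_class), levels = classes)

  # per-probe, per-class means
  mu <- stats::runif(p, 0.2, 0.8)
  class_means <- matrix(mu, nrow = p, ncol = k,
                        dimnames = list(probe_ids, classes))
  inf_idx <- sort(sample.int(p, spec$n_informative))
  if (spec$n_informative > 0) {
    offsets <- delta * stats::setNames(
      c(0, as.vector(rbind(seq_len(k), -seq_len(k))))[seq_len(k)], NULL)
    for (j in inf_idx) {
      class_means[j, ] <- pmin(0.95, pmax(0.05, mu[j] + sample(offsets)))
    }
  }
  if (any(class_means <= 0 | class_means >= 1))
    stop("effect/concentration combination yields class means outside (0,1)")

  # values: Beta(mean * s, (1 - mean) * s), one draw per [sample, probe]
  mean_mat <- t(class_means)[as.integer(labels), , drop = FALSE]  # n x p
  values <- matrix(stats::rbeta(n * p, mean_mat * s, (1 - mean_mat) * s),
                   nrow = n, ncol = p,
                   dimnames = list(sample_ids, probe_ids))
  # rbeta can return exact 0/1 only for degenerate shapes; clamp epsilon
  values <- pmin(pmax(values, 1e-9), 1 - 1e-9)  # arg order keeps dimnames
  dataset <- methyl_dataset(values,
                            labels = stats::setNames(labels, sample_ids))

  # annotation: one distinct planted gene per informative probe; noise
  # probes unannotated with the spec's fraction, else 1..max filler genes
  planted_genes <- sprintf("GENE_P%04d", seq_len(spec$n_informative))
  filler_pool <- sprintf("GENE_F%05d", seq_len(spec$n_filler_genes))
  genes <- vector("list", p)
  names(genes) <- probe_ids
  genes[inf_idx] <- as.list(planted_genes)
  noise_idx <- setdiff(seq_len(p), inf_idx)
  unann <- stats::runif(length(noise_idx)) < spec$frac_unannotated
  size_probs <- 4^-(seq_len(spec$max_genes_per_probe) - 1)
  n_genes <- sample(spec$max_genes_per_probe, length(noise_idx),
                    replace = TRUE, prob = size_probs / sum(size_probs))
  for (i in seq_along(noise_idx)) {
    genes[[noise_idx[i]]] <- if (unann[i]) character(0) else
      sample(filler_pool, n_genes[i])
  }
  annotation <- probe_annotation(genes)

  # term map: the planted term plus random filler terms
  term_size <- spec$planted_term_size %||% spec$n_informative
  planted_set <- planted_genes
  if (term_size > length(planted_set))
    planted_set <- c(planted_set,
                     sample(filler_pool, term_size - length(planted_set)))
  tm_genes <- list()
  tm_names <- character(0)
  if (spec$n_informative > 0) {
    tm_genes[["TERM_PLANTED"]] <- planted_set
    tm_names["TERM_PLANTED"] <- "planted discriminative gene set"
  }
  for (i in seq_len(spec$n_filler_terms)) {
    id <- sprintf("TERM_F%03d", i)
    sz <- sample(5:40, 1)
    tm_genes[[id]] <- sample(filler_pool, min(sz, length(filler_pool)))
    tm_names[id] <- sprintf("filler term %d", i)
  }
  terms <- term_map(tm_genes, tm_names)

  truth <- list(informative_probe_ids = probe_ids[inf_idx],
                class_means = class_means[inf_idx, , drop = FALSE],
                planted_term_id = if (spec$n_informative > 0) "TERM_PLANTED"
                                  else NA_character_,
                planted_genes = planted_genes)
  structure(list(dataset = dataset, annotation = annotation,
                 terms = terms, truth = truth, spec = spec),
            class = "synthetic_methylation")
}

#' @export
print.synthetic_methylation <- function(x, ...) {
  cat("synthetic_methylation world\n")
  print(x$dataset)
  cat(sprintf("  planted probes: %d; planted term: %s (%d genes)\n",
              length(x$truth$informative_probe_ids),
              x$truth$planted_term_id, length(x$truth$planted_genes)))
  invisible(x)
}

#' Write all artifacts of a synthetic world to a directory
#'
#' Emits \code{matrix.tsv}, \code{labels.tsv}, \code{annotation.tsv},
#' \code{terms.gmt} and \code{truth.json}.
#'
#' @param world a \code{\link{generate_dataset}} result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_methylation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(world$dataset, file.path(dir, "matrix.tsv"))
  write_labels(dataset_labels(world$dataset), file.path(dir, "labels.tsv"))
  write_probe_annotation(world$annotation, file.path(dir, "annotation.tsv"))
  write_gmt(world$terms, file.path(dir, "terms.gmt"))
  truth <- world$truth
  truth$class_means <- NULL  # matrices don't round-trip cleanly in JSON
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
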