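#' Probe-to-gene annotation
#'
#' Maps each probe id to a (possibly empty) set of gene symbols, mirroring
#' the 450K platform's \code{UCSC_RefGene_Name} dialect: a probe in an
#' intergenic region maps to no gene at all, others to one or several
#' symbols.
#'
#' @param genes named list; names are probe ids, elements are character
#'   vectors of gene symbols (possibly empty). Duplicate symbols within a
#'   probe are collapsed.
#' @return an object of class \code{"probe_annotation"}.
#' @export
probe_annotation <- function(genes) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  check_ids(names(genes), "probe")
  genes <- lapply(genes, function(g) {
    g <- unique(trimws(as.character(g)))
    g <- g[nzchar(g)]
    g
  })
  structure(genes, class = "probe_annotation")
}

#' @export
print.probe_annotation <- function(x, ...) {
  nz <- sum(lengths(x) > 0)
  cat(sprintf("probe_annotation: %d probes (%d annotated, %d intergenic), %d distinct genes\n",
              length(x), nz, length(x) - nz,
              length(unique(unlist(x)))))
  invisible(x)
}

#' Read a probe annotation table
#'
#' TSV with columns \code{(probe_id, gene_field)} where the gene field is
#' a semicolon-separated symbol list, possibly empty.
#'
#' @param path TSV path.
#' @return a \code{\link{probe_annotation}}.
#' @export
read_probe_annotation <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    stop(sprintf("'%s': annotation needs columns (probe_id, genes)", path))
  ids <- trimws(as.character(df[[1]]))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop(sprintf("'%s': duplicated probe row(s): %s", path,
                 paste(utils::head(unique(dup), 5), collapse = ", ")))
  genes <- strsplit(as.character(df[[2]]), ";", fixed = TRUE)
  names(genes) <- ids
  probe_annotation(genes)
}

#' @rdname read_probe_annotation
#' @param annotation a \code{probe_annotation}.
#' @export
write_probe_annotation <- function(annotation, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("probe_id\tgenes", con)
  writeLines(paste(names(annotation),
                   vapply(annotation, paste, "", collapse = ";"),
                   sep = "\t"), con)
  invisible(path)
}

#' Gene-set term map
#'
#' @param genes named list of character vectors (term id -> gene set);
#'   every term must have at least one gene.
#' @param term_names optional named character vector of human-readable
#'   names; defaults to the term ids.
#' @return an object of class \code{"term_map"}.
#' @export
term_map <- function(genes, term_names = NULL) {
  stopifnot(is.list(genes))
  if (length(genes) > 0) {
    check_ids(names(genes), "term")
    genes <- lapply(genes, function(g) {
      g <- unique(trimws(as.character(g)))
      g[nzchar(g)]
    })
    if (any(lengths(genes) == 0))
      stop(sprintf("term(s) with no genes: %s",
                   paste(utils::head(names(genes)[lengths(genes) == 0], 5),
                         collapse = ", ")))
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(genes), names(genes))
  } else {
    term_names <- stats::setNames(as.character(term_names[names(genes)]),
                                  names(genes))
    term_names[is.na(term_names)] <- names(genes)[is.na(term_names)]
  }
  structure(genes, term_names = term_names, class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("term_map: %d terms, gene-set sizes %s\n", length(x),
              if (length(x) > 0)
                paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT: one term per line, tab-separated
#' \code{term_id <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#'
#' @param path GMT path.
#' @return a \code{\link{term_map}}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(term_map(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop(sprintf("'%s': GMT line %d has %d field(s); need term, description, >=1 gene",
                 path, short[1], lengths(parts)[short[1]]))
  ids <- trimws(vapply(parts, `[[`, "", 1))
  descr <- stats::setNames(trimws(vapply(parts, `[[`, "", 2)), ids)
  genes <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  term_map(genes, descr)
}

#' @rdname read_gmt
#' @param terms a \code{term_map}.
#' @export
write_gmt <- function(terms, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  nm <- attr(terms, "term_names")
  if (length(terms) > 0)
    writeLines(vapply(names(terms), function(id) {
      paste(c(id, nm[[id]], terms[[id]]), collapse = "\t")
    }, ""), con)
  invisible(path)
}
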