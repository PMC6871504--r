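#' Read a beta-value matrix from TSV
#'
#' Reads a tab-delimited matrix with one header row and one leading id
#' column. Lines starting with \code{#} are ignored. GEO series-matrix
#' exports are probes-as-rows; the internal orientation is always
#' \code{[sample, probe]}, so probes-as-rows input is transposed on load.
#'
#' @param path TSV file path.
#' @param orientation \code{"probes"} if rows are probes (default,
#'   series-matrix convention) or \code{"samples"} if rows are samples.
#' @param drop_incomplete_probes if \code{TRUE}, probes with one or more
#'   missing/non-numeric values are removed (with a warning) before
#'   validation instead of raising an error. No imputation is ever done:
#'   silent imputation would change downstream importance scores
#'   invisibly.
#' @return an unlabeled \code{\link{methyl_dataset}}.
#' @export
read_beta_matrix <- function(path, orientation = c("probes", "samples"),
                             drop_incomplete_probes = FALSE) {
  orientation <- match.arg(orientation)
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    stop(sprintf("'%s': need an id column plus at least one data column", path))
  ids <- trimws(as.character(df[[1]]))
  check_ids(ids, if (orientation == "probes") "probe" else "sample")
  body <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(body) <- "character"
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  rownames(num) <- ids
  colnames(num) <- trimws(colnames(df)[-1])
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    bad_rows <- unique(bad[, 1])
    if (drop_incomplete_probes && orientation == "probes") {
      warning(sprintf("dropping %d probe(s) with missing values: %s",
                      length(bad_rows),
                      paste(utils::head(rownames(num)[bad_rows], 5),
                            collapse = ", ")))
      num <- num[-bad_rows, , drop = FALSE]
    } else if (drop_incomplete_probes) {
      bad_cols <- unique(bad[, 2])
      warning(sprintf("dropping %d probe(s) with missing values: %s",
                      length(bad_cols),
                      paste(utils::head(colnames(num)[bad_cols], 5),
                            collapse = ", ")))
      num <- num[, -bad_cols, drop = FALSE]
    } else {
      pr <- if (orientation == "probes") rownames(num)[bad[1, 1]] else colnames(num)[bad[1, 2]]
      sa <- if (orientation == "probes") colnames(num)[bad[1, 2]] else rownames(num)[bad[1, 1]]
      stop(sprintf("'%s': non-numeric or missing value at probe '%s', sample '%s'",
                   path, pr, sa))
    }
  }
  if (orientation == "probes") num <- t(num)
  methyl_dataset(num)
}

#' Write a beta-value matrix to TSV
#'
#' Reals are serialized with 6 decimals so outputs are byte-stable.
#'
#' @param dataset a \code{\link{methyl_dataset}}.
#' @param path output path.
#' @param orientation row entity of the written file (default probes).
#' @export
write_beta_matrix <- function(dataset, path,
                              orientation = c("probes", "samples")) {
  orientation <- match.arg(orientation)
  m <- unclass(dataset)
  attr(m, "labels") <- NULL
  if (orientation == "probes") m <- t(m)
  id_col <- if (orientation == "probes") "probe_id" else "sample_id"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 2, function(col) sprintf("%.6f", col))
  writeLines(paste(rownames(m), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a sample label file
#'
#' Two-column TSV \code{(sample_id, class)} with a header row.
#'
#' @param path TSV path.
#' @return named character vector, sample id to class.
#' @export
read_labels <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    stop(sprintf("'%s': label file needs columns (sample_id, class)", path))
  ids <- trimws(as.character(df[[1]]))
  check_ids(ids, "sample")
  stats::setNames(trimws(as.character(df[[2]])), ids)
}

#' @rdname read_labels
#' @param labels named character/factor vector (names = sample ids).
#' @export
write_labels <- function(labels, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("sample_id\tclass", con)
  writeLines(paste(names(labels), as.character(labels), sep = "\t"), con)
  invisible(path)
}

#' Write / read a ranked probe list
#'
#' TSV columns \code{(rank, probe_id, ri)}; RI serialized to 6 decimals.
#'
#' @param ranked a \code{\link{mcfs_rank}} result (or any data frame with
#'   \code{probe_id} and \code{ri} columns in rank order).
#' @param path TSV path.
#' @export
write_ranked_list <- function(ranked, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("rank\tprobe_id\tri", con)
  if (nrow(ranked) > 0)
    writeLines(sprintf("%d\t%s\t%.6f", seq_len(nrow(ranked)),
                       ranked$probe_id, ranked$ri), con)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("probe_id", "ri")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s': ranked list needs columns (rank, probe_id, ri)", path))
  out <- data.frame(probe_id = trimws(as.character(df$probe_id)),
                    ri = as.numeric(df$ri), stringsAsFactors = FALSE)
  check_ids(out$probe_id, "probe")
  if (is.unsorted(rev(out$ri)))
    stop(sprintf("'%s': ri column must be non-increasing", path))
  class(out) <- c("mcfs_ranking", "data.frame")
  out
}

#' Write / read an IFS curve
#'
#' TSV columns \code{(k, acc_<class>..., overall_acc, mcc)}.
#'
#' @param curve an \code{\link{ifs_curve}}.
#' @param path TSV path.
#' @export
write_ifs_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "k"
  for (j in which(num)) df[[j]] <- sprintf("%.6f", df[[j]])
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
read_ifs_curve <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("k", "overall_acc", "mcc") %in% names(df)))
    stop(sprintf("'%s': not an IFS curve file", path))
  for (j in seq_along(df)) df[[j]] <- as.numeric(df[[j]])
  df$k <- as.integer(df$k)
  class(df) <- c("ifs_curve", "data.frame")
  df
}

#' Write an enrichment table
#'
#' TSV columns \code{(term_id, name, k, K, n, N, p, fdr, significant)}.
#'
#' @param table an \code{\link{enrich}} result.
#' @param path TSV path.
#' @export
write_enrichment <- function(table, path) {
  df <- as.data.frame(table)
  df$p <- sprintf("%.6g", df$p)
  df$fdr <- sprintf("%.6g", df$fdr)
  df$significant <- ifelse(df$significant, "TRUE", "FALSE")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

# Strict TSV reader: UTF-8, '#' comment lines ignored, header row kept
# verbatim, ragged rows rejected with the offending line number.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop(sprintf("'%s': empty file", path))
  # sentinel keeps trailing empty fields (strsplit drops them)
  parts <- strsplit(paste0(lines, "\v"), "\t", fixed = TRUE)
  parts <- lapply(parts, function(p) { p[length(p)] <- sub("\v$", "", p[length(p)]); p })
  nfield <- lengths(parts)
  if (any(nfield != nfield[1])) {
    bad <- which(nfield != nfield[1])[1]
    stop(sprintf("'%s': ragged row %d has %d fields, header has %d",
                 path, bad, nfield[bad], nfield[1]))
  }
  header <- parts[[1]]
  body <- parts[-1]
  df <- as.data.frame(do.call(rbind, c(body, list(deparse.level = 0))),
                      stringsAsFactors = FALSE)
  if (length(body) == 0)
    df <- as.data.frame(matrix(character(0), 0, length(header)),
                        stringsAsFactors = FALSE)
  names(df) <- trimws(header)
  df
}
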