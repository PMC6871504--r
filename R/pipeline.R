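#' Build a validated pipeline run configuration
#'
#' A run either simulates its inputs (\code{simulate = TRUE}, using the
#' synthetic-world fields) or loads them from \code{matrix}, \code{labels},
#' \code{annotation} and \code{gmt} paths. One master seed fans out to
#' fixed per-stage seeds, so any stage can be re-run in isolation
#' reproducibly and two runs with the same configuration produce
#' byte-identical artifacts.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master integer seed (mandatory).
#' @param simulate if TRUE generate inputs with
#'   \code{\link{generate_dataset}}.
#' @param matrix,labels,annotation,gmt input paths (ignored when
#'   simulating).
#' @param n_per_class,n_probes,n_informative,effect,concentration
#'   synthetic-world fields, see \code{\link{synthetic_spec}}.
#' @param t,m,subset_size,u,v MCFS fields, see \code{\link{mcfs_params}}.
#' @param folds,stratified cross-validation fields.
#' @param classifiers character vector of registered adapter ids.
#' @param step IFS prefix step.
#' @param tol compact-selection MCC tolerance.
#' @param fdr enrichment significance threshold.
#' @param max_k optional cap on the largest IFS prefix.
#' @param enrich_k override the feature count fed to enrichment (default:
#'   the optimum prefix of the best classifier).
#' @param universe \code{"platform"} (genes of all probes on the matrix;
#'   conservative default) or \code{"positive-ri"} (genes of positive-RI
#'   probes only).
#' @param min_term_size minimum universe genes per tested term.
#' @param drop_incomplete_probes forward to \code{\link{read_beta_matrix}}.
#' @return an object of class \code{"run_config"}.
#' @export
run_config <- function(out_dir, seed, simulate = FALSE,
                       matrix = NULL, labels = NULL, annotation = NULL,
                       gmt = NULL,
                       n_per_class = c(A = 78L, B = 46L, C = 80L),
                       n_probes = 2000L, n_informative = 20L,
                       effect = 0.25, concentration = 30,
                       t = 100L, m = 5L, subset_size = NULL, u = 1, v = 1,
                       folds = 10L, stratified = TRUE,
                       classifiers = "svm_ovr_linear",
                       step = 10L, tol = 0.01, fdr = 0.05,
                       max_k = NULL, enrich_k = NULL,
                       universe = c("platform", "positive-ri"),
                       min_term_size = 2L,
                       drop_incomplete_probes = FALSE) {
  if (missing(seed) || is.null(seed)) stop("config: 'seed' is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("config: 'seed' must be an integer")
  universe <- match.arg(universe)
  if (tol < 0) stop("config: 'tol' must be >= 0")
  if (fdr <= 0 || fdr > 1) stop("config: 'fdr' must be in (0, 1]")
  if (!simulate) {
    paths <- list(matrix = matrix, labels = labels,
                  annotation = annotation, gmt = gmt)
    miss <- names(paths)[vapply(paths, is.null, TRUE)]
    if (length(miss) > 0)
      stop(sprintf("config: missing input path(s): %s",
                   paste(miss, collapse = ", ")))
    absent <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(absent) > 0)
      stop(sprintf("config: input file(s) not found: %s",
                   paste(absent, collapse = ", ")))
  }
  for (cl in classifiers) get_classifier(cl)  # fail early on unknown ids
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 matrix = matrix, labels = labels, annotation = annotation,
                 gmt = gmt, n_per_class = n_per_class, n_probes = n_probes,
                 n_informative = n_informative, effect = effect,
                 concentration = concentration,
                 t = t, m = m, subset_size = subset_size, u = u, v = v,
                 folds = folds, stratified = stratified,
                 classifiers = classifiers, step = step, tol = tol,
                 fdr = fdr, max_k = max_k, enrich_k = enrich_k,
                 universe = universe, min_term_size = min_term_size,
                 drop_incomplete_probes = drop_incomplete_probes),
            class = "run_config")
}

#' Read and validate a pipeline configuration file
#'
#' Flat \code{key = value} text (\code{#} comments allowed). Unknown keys
#' are an error; all values are type-checked by \code{\link{run_config}}.
#' \code{n_per_class} is written as \code{A=30,B=20,C=30};
#' \code{classifiers} as a comma-separated list.
#'
#' @param path config file path.
#' @return a validated \code{\link{run_config}}.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0)
    stop(sprintf("config: cannot parse line: '%s'", lines[bad[1]]))
  keys <- vapply(kv, `[[`, "", 2)
  vals <- trimws(vapply(kv, `[[`, "", 3))
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0)
    stop(sprintf("config: duplicate key(s): %s", paste(dup, collapse = ", ")))
  known <- setdiff(names(formals(run_config)), "...")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop(sprintf("config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  args <- stats::setNames(as.list(vals), keys)
  num_keys <- c("seed", "n_probes", "n_informative", "effect",
                "concentration", "t", "m", "subset_size", "u", "v",
                "folds", "step", "tol", "fdr", "max_k", "enrich_k",
                "min_term_size")
  lgl_keys <- c("simulate", "stratified", "drop_incomplete_probes")
  for (ky in names(args)) {
    if (ky %in% num_keys) {
      x <- suppressWarnings(as.numeric(args[[ky]]))
      if (is.na(x)) stop(sprintf("config: '%s' must be numeric, got '%s'",
                                 ky, args[[ky]]))
      args[[ky]] <- x
    } else if (ky %in% lgl_keys) {
      if (!tolower(args[[ky]]) %in% c("true", "false"))
        stop(sprintf("config: '%s' must be true/false", ky))
      args[[ky]] <- tolower(args[[ky]]) == "true"
    } else if (ky == "n_per_class") {
      parts <- strsplit(args[[ky]], ",", fixed = TRUE)[[1]]
      m2 <- regmatches(parts, regexec("^\\s*(\\S+)\\s*=\\s*(\\d+)\\s*$", parts))
      if (any(lengths(m2) != 3))
        stop("config: n_per_class must look like 'A=30,B=20,C=30'")
      args[[ky]] <- stats::setNames(
        as.integer(vapply(m2, `[[`, "", 3)),
        vapply(m2, `[[`, "", 2))
    } else if (ky == "classifiers") {
      args[[ky]] <- trimws(strsplit(args[[ky]], ",", fixed = TRUE)[[1]])
    }
  }
  do.call(run_config, args)
}

derive_seed <- function(master, idx) {
  as.integer((as.double(master) * 48271 + idx * 9973) %% 2147483629 + 1)
}

#' Run the full subtype-discovery pipeline
#'
#' Executes simulate/load, MCFS ranking, the positive-RI filter, IFS per
#' classifier, optimum/compact selection, probe-to-gene mapping of the
#' optimum prefix (of the best-performing classifier) and term
#' enrichment, writing every artifact plus a JSON run manifest (config
#' echo, package version, per-stage timings and artifact checksums) to
#' \code{config$out_dir}. The manifest is written even when a stage
#' fails, recording the failing stage.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose log stage progress (default TRUE).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("methylMCFS")),
    config = config[setdiff(names(config), "")],
    stages = list(), artifacts = list(), warnings = character(0))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  finish <- function() {
    manifest$artifacts <- as.list(tools::md5sum(
      list.files(config$out_dir, full.names = TRUE, pattern = "\\.(tsv|gmt|json|txt)$")))
    names(manifest$artifacts) <- basename(names(manifest$artifacts))
    manifest$artifacts[["manifest.json"]] <- NULL
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        finish()
        stop(sprintf("pipeline stage '%s' failed: %s", name,
                     conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  # -- inputs ----------------------------------------------------------
  world <- stage("inputs", {
    if (config$simulate) {
      say("simulating synthetic world (seed %d)", derive_seed(config$seed, 1))
      w <- generate_dataset(synthetic_spec(
        n_per_class = config$n_per_class, n_probes = config$n_probes,
        n_informative = config$n_informative, effect = config$effect,
        concentration = config$concentration,
        seed = derive_seed(config$seed, 1)))
      write_synthetic(w, file.path(config$out_dir, "inputs"))
      w
    } else {
      say("loading inputs")
      ds <- read_beta_matrix(config$matrix,
                             drop_incomplete_probes = config$drop_incomplete_probes)
      ds <- attach_labels(ds, read_labels(config$labels))
      list(dataset = ds,
           annotation = read_probe_annotation(config$annotation),
           terms = read_gmt(config$gmt), truth = NULL)
    }
  })
  dataset <- world$dataset

  # -- MCFS ranking ----------------------------------------------------
  ranked <- stage("mcfs_rank", {
    say("ranking %d probes (t=%d, m=%d)", n_probes(dataset), config$t, config$m)
    mcfs_rank(dataset, mcfs_params(
      t = config$t, m = config$m, subset_size = config$subset_size,
      u = config$u, v = config$v, seed = derive_seed(config$seed, 2)))
  })
  write_ranked_list(ranked, file.path(config$out_dir, "ranked.tsv"))

  positive <- stage("filter_positive_ri", filter_positive_ri(ranked))
  say("%d / %d probes with RI > 0", nrow(positive), nrow(ranked))
  if (nrow(positive) == 0) {
    stage("ifs", stop("no probe has positive RI; nothing to select"))
  }

  # -- IFS per classifier ----------------------------------------------
  selections <- list()
  curves <- list()
  for (clf in config$classifiers) {
    curve <- stage(paste0("ifs_", clf), {
      say("IFS with %s", clf)
      run_ifs(dataset, positive, classifier = clf,
              cv = cv_spec(config$folds, config$stratified,
                           derive_seed(config$seed, 3)),
              step = config$step, max_k = config$max_k, verbose = verbose)
    })
    curves[[clf]] <- curve
    write_ifs_curve(curve, file.path(config$out_dir,
                                     sprintf("curve_%s.tsv", clf)))
    opt <- select_optimum(curve)
    cmp <- select_compact(curve, config$tol)
    selections[[clf]] <- data.frame(
      classifier = clf,
      which = c("optimum", "compact"),
      k = c(opt$k, cmp$k),
      overall_acc = c(opt$overall_acc, cmp$overall_acc),
      mcc = c(opt$mcc, cmp$mcc), stringsAsFactors = FALSE)
  }
  seldf <- do.call(rbind, selections)
  rownames(seldf) <- NULL
  utils::write.table(
    within(seldf, {mcc <- sprintf("%.6f", mcc)
                   overall_acc <- sprintf("%.6f", overall_acc)}),
    file.path(config$out_dir, "selection.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # -- enrichment on the optimum prefix --------------------------------
  enr <- stage("enrichment", {
    opt_rows <- seldf[seldf$which == "optimum", , drop = FALSE]
    best <- opt_rows[which.max(opt_rows$mcc), ]
    k_use <- config$enrich_k %||% best$k
    say("enrichment on top %d probes (classifier %s)", k_use, best$classifier)
    sel_probes <- positive$probe_id[seq_len(min(k_use, nrow(positive)))]
    sel_genes <- probes_to_genes(sel_probes, world$annotation)
    uni_probes <- if (config$universe == "platform") colnames(dataset)
                  else positive$probe_id
    uni_genes <- probes_to_genes(uni_probes, world$annotation)
    writeLines(sel_genes, file.path(config$out_dir, "selected_genes.txt"))
    enrich(sel_genes, uni_genes, world$terms,
           fdr_threshold = config$fdr, min_term_size = config$min_term_size)
  })
  write_enrichment(enr, file.path(config$out_dir, "enrichment.tsv"))

  manifest$selection <- seldf
  finish()
  say("pipeline complete: %s", config$out_dir)
  invisible(manifest)
}
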