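#' Cross-validation specification
#'
#' @param n_folds number of folds (default 10).
#' @param stratified preserve class proportions per fold (default TRUE;
#'   keeps minority classes represented in every fold under imbalance).
#' @param seed integer seed for the fold assignment and classifier fits.
#' @return an object of class \code{"cv_spec"}.
#' @export
cv_spec <- function(n_folds = 10L, stratified = TRUE, seed = 1L) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), stratified = stratified,
                 seed = as.integer(seed)), class = "cv_spec")
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of \code{n_folds} folds so that per-class
#' fold counts differ by at most one AND total fold sizes differ by at
#' most one (each class's remainder samples go to the currently smallest
#' folds). Deterministic given the seed.
#'
#' @param labels factor (or coercible) of class labels.
#' @param cv a \code{\link{cv_spec}}; with \code{stratified = FALSE}
#'   samples are dealt out irrespective of class.
#' @return integer vector of fold ids in \code{1..n_folds}.
#' @export
stratified_folds <- function(labels, cv = cv_spec()) {
  labels <- as.factor(labels)
  nf <- cv$n_folds
  set.seed(cv$seed)
  fold <- integer(length(labels))
  if (!cv$stratified) {
    idx <- sample.int(length(labels))
    fold[idx] <- rep_len(seq_len(nf), length(labels))
    return(fold)
  }
  tab <- table(labels)
  if (any(tab < nf))
    stop(sprintf(
      "class '%s' has %d sample(s) < %d folds; use fewer folds",
      names(tab)[which.min(tab)], min(tab), nf))
  totals <- integer(nf)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% nf
    rem <- length(idx) %% nf
    sizes <- rep(base, nf)
    if (rem > 0) {
      extra <- order(totals, seq_len(nf))[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    fold[idx] <- rep(seq_len(nf), times = sizes)
    totals <- totals + sizes
  }
  fold
}

# ---- classifier adapter registry -------------------------------------
#
# An adapter is a list(fit, predict, defaults):
#   fit(x, y, params, seed) -> model   (x: numeric matrix, y: factor)
#   predict(model, x) -> factor with the training levels
# Registered adapters must be deterministic given the seed. External
# rule learners (e.g. a RIPPER wrapper) can be plugged in through
# register_classifier() and validated with validate_classifier_adapter().

.classifiers <- new.env(parent = emptyenv())

#' Register / look up classifier adapters
#'
#' @param id adapter identifier string.
#' @param adapter list with functions \code{fit(x, y, params, seed)} and
#'   \code{predict(model, x)}, plus a \code{defaults} parameter list.
#' @export
register_classifier <- function(id, adapter) {
  stopifnot(is.character(id), length(id) == 1,
            is.list(adapter), is.function(adapter$fit),
            is.function(adapter$predict))
  if (is.null(adapter$defaults)) adapter$defaults <- list()
  assign(id, adapter, envir = .classifiers)
  invisible(id)
}

#' @rdname register_classifier
#' @export
list_classifiers <- function() sort(ls(.classifiers))

#' @rdname register_classifier
#' @export
get_classifier <- function(id) {
  if (!exists(id, envir = .classifiers, inherits = FALSE))
    stop(sprintf("unknown classifier '%s'; registered: %s", id,
                 paste(list_classifiers(), collapse = ", ")))
  get(id, envir = .classifiers, inherits = FALSE)
}

#' Classifier specification
#'
#' @param id a registered adapter id (\code{"svm_ovr_linear"} and
#'   \code{"random_forest"} ship with the package).
#' @param ... hyperparameter overrides merged over the adapter defaults
#'   (SVM: \code{C} = 1, \code{scale} = TRUE for per-feature min-max
#'   scaling fitted on training data; RF: \code{n_trees} = 100,
#'   \code{mtry} = floor(sqrt(p))).
#' @return an object of class \code{"classifier_spec"}.
#' @export
classifier_spec <- function(id = "svm_ovr_linear", ...) {
  adapter <- get_classifier(id)
  params <- utils::modifyList(adapter$defaults, list(...))
  structure(list(id = id, params = params), class = "classifier_spec")
}

as_classifier_spec <- function(x) {
  if (inherits(x, "classifier_spec")) x else classifier_spec(x)
}

# ---- linear one-vs-rest SVM ------------------------------------------
# L2-regularized squared-hinge linear SVM (the L2L2 primal), solved with
# BFGS; deterministic, no RNG. One binary machine per class against the
# rest, prediction by maximal decision value, ties to the first (alpha-
# betically smallest) class level.

svm_binary_fit <- function(x, y2, C) {
  p <- ncol(x)
  obj <- function(wb) {
    w <- wb[seq_len(p)]
    marg <- 1 - y2 * (drop(x %*% w) + wb[p + 1])
    viol <- pmax(marg, 0)
    0.5 * sum(w^2) + C * sum(viol^2)
  }
  grad <- function(wb) {
    w <- wb[seq_len(p)]
    marg <- 1 - y2 * (drop(x %*% w) + wb[p + 1])
    viol <- pmax(marg, 0)
    c(w - 2 * C * drop(crossprod(x, y2 * viol)),
      -2 * C * sum(y2 * viol))
  }
  fit <- stats::optim(numeric(p + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1])
}

svm_adapter <- list(
  defaults = list(C = 1, scale = TRUE),
  fit = function(x, y, params, seed) {
    y <- droplevels(as.factor(y))
    if (nlevels(y) < 2) stop("svm_ovr_linear needs >= 2 classes in training data")
    scaling <- NULL
    if (isTRUE(params$scale)) {
      lo <- apply(x, 2, min)
      hi <- apply(x, 2, max)
      span <- hi - lo
      span[span == 0] <- 1   # constant feature -> maps to 0
      scaling <- list(lo = lo, span = span)
      x <- sweep(sweep(x, 2, lo), 2, span, "/")
    }
    machines <- lapply(levels(y), function(cl) {
      svm_binary_fit(x, ifelse(y == cl, 1, -1), params$C)
    })
    list(machines = machines, levels = levels(y), scaling = scaling)
  },
  predict = function(model, x) {
    if (!is.null(model$scaling))
      x <- sweep(sweep(x, 2, model$scaling$lo), 2, model$scaling$span, "/")
    dec <- vapply(model$machines,
                  function(mch) drop(x %*% mch$w) + mch$b,
                  numeric(nrow(x)))
    dec <- matrix(dec, nrow = nrow(x))
    factor(model$levels[apply(dec, 1, which.max)], levels = model$levels)
  }
)

# ---- random forest ---------------------------------------------------
# Bagged entropy trees with per-node feature subsampling (mtry =
# floor(sqrt(p)) by default) and majority vote; seeded, hence
# deterministic.

rf_adapter <- list(
  defaults = list(n_trees = 100L, mtry = NULL, min_split = 2L),
  fit = function(x, y, params, seed) {
    y <- droplevels(as.factor(y))
    set.seed(as.integer(seed))
    mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(x))))
    n <- nrow(x)
    trees <- lapply(seq_len(params$n_trees), function(i) {
      boot <- sample.int(n, n, replace = TRUE)
      grow_tree(x[boot, , drop = FALSE], y[boot],
                min_split = params$min_split, mtry = mtry)
    })
    list(trees = trees, levels = levels(y))
  },
  predict = function(model, x) {
    k <- length(model$levels)
    votes <- matrix(0L, nrow(x), k)
    for (tr in model$trees) {
      pr <- as.integer(predict(tr, x))
      votes[cbind(seq_len(nrow(x)), pr)] <-
        votes[cbind(seq_len(nrow(x)), pr)] + 1L
    }
    factor(model$levels[apply(votes, 1, which.max)], levels = model$levels)
  }
)

#' Check an adapter against the classifier contract
#'
#' Fits and predicts on a small random two-class problem and verifies the
#' contract every registered adapter must satisfy: predictions are a
#' factor over the training levels with one value per row, and repeated
#' fits under the same seed give identical predictions.
#'
#' @param id registered adapter id.
#' @param n samples in the probe problem (default 40).
#' @param seed RNG seed.
#' @return TRUE invisibly; errors describe the first violated clause.
#' @export
validate_classifier_adapter <- function(id, n = 40L, seed = 1L) {
  adapter <- get_classifier(id)
  params <- classifier_spec(id)$params
  set.seed(seed)
  x <- matrix(stats::runif(n * 5), n, 5)
  y <- factor(rep(c("a", "b"), length.out = n))
  m1 <- adapter$fit(x, y, params, seed)
  p1 <- adapter$predict(m1, x)
  if (!is.factor(p1) || length(p1) != n)
    stop(sprintf("'%s': predict must return a factor of length nrow(x)", id))
  if (!identical(levels(p1), levels(y)))
    stop(sprintf("'%s': prediction levels must equal training levels", id))
  m2 <- adapter$fit(x, y, params, seed)
  p2 <- adapter$predict(m2, x)
  if (!identical(p1, p2))
    stop(sprintf("'%s': not deterministic under a fixed seed", id))
  invisible(TRUE)
}
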