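# fold building, multiclass metrics, prefix evaluation and selection

test_that("multiclass MCC matches its closed form and the binary special case", {
  expect_equal(multiclass_mcc(diag(c(10, 10, 10))), 1.0)
  one_col <- matrix(0, 3, 3); one_col[, 1] <- c(4, 3, 3)
  expect_equal(multiclass_mcc(one_col), 0.0)       # degenerate margins
  expect_equal(multiclass_mcc(matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 3), 3)),
               36 / 54, tolerance = 1e-12)

  # R_K == binary MCC on 2x2, checked over random matrices
  set.seed(1)
  for (i in 1:200) {
    m <- matrix(rpois(4, 5), 2)
    if (sum(m) == 0) next
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    binary <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(multiclass_mcc(m), binary, tolerance = 1e-12)
  }
  # bounded in [-1, 1] on random 3x3 / 4x4
  for (i in 1:100) {
    k <- sample(3:4, 1)
    m <- matrix(rpois(k * k, 3), k)
    if (sum(m) == 0) next
    expect_true(abs(multiclass_mcc(m)) <= 1 + 1e-12)
  }
})

test_that("accuracies match hand counts and flag empty classes", {
  a <- accuracies(diag(c(5, 5)))
  expect_equal(unname(a$per_class), c(1, 1))
  expect_equal(a$overall, 1)
  a2 <- accuracies(matrix(c(8, 5, 2, 5), 2,
                          dimnames = list(c("c1", "c2"), c("c1", "c2"))))
  expect_equal(a2$per_class, c(c1 = 0.8, c2 = 0.5))
  expect_equal(a2$overall, 0.65)
  # overall == class-size-weighted mean of per-class accuracies
  set.seed(2)
  m <- matrix(rpois(9, 4), 3)
  a3 <- accuracies(m)
  expect_equal(a3$overall,
               sum(a3$per_class * rowSums(m), na.rm = TRUE) / sum(m))
  expect_true(is.na(accuracies(rbind(c(0, 0), c(1, 1)))$per_class[1]))
})

test_that("stratified folds balance classes and totals", {
  lab <- factor(rep(c("A", "B", "C"), each = 10))
  f <- stratified_folds(lab, cv_spec(10, TRUE, 1))
  expect_true(all(table(lab, f) == 1))
  expect_identical(f, stratified_folds(lab, cv_spec(10, TRUE, 1)))
  expect_false(identical(f, stratified_folds(lab, cv_spec(10, TRUE, 2))))

  lab2 <- factor(rep(c("A", "B", "C"), times = c(78, 46, 80)))
  f2 <- stratified_folds(lab2, cv_spec(10, TRUE, 3))
  per_class <- table(lab2, f2)
  expect_true(all(apply(per_class, 1, function(r) diff(range(r)) <= 1)))
  expect_lte(diff(range(table(f2))), 1)

  expect_error(stratified_folds(factor(rep(c("A", "B"), c(5, 30))),
               cv_spec(10, TRUE, 1)), "fewer folds")
})

test_that("prefix sizes follow the step-of-10 construction", {
  expect_equal(make_prefix_sizes(25, 10), c(10L, 20L, 25L))
  expect_equal(make_prefix_sizes(7, 10), 7L)
  expect_equal(make_prefix_sizes(30, 10), c(10L, 20L, 30L))
  ks <- make_prefix_sizes(19692, 10)
  expect_true(all(c(750L, 1330L, 19270L) %in% ks))
  expect_equal(ks[length(ks)], 19692L)
  expect_equal(ks[length(ks) - 1], 19690L)
  expect_true(all(diff(ks) > 0))
})

test_that("evaluate_prefix pools folds, conserves counts, and is deterministic", {
  w <- tiny_world(seed = 7)
  ranked <- mcfs_rank(w$dataset, mcfs_params(t = 20, m = 2, seed = 1))
  cv <- cv_spec(6, TRUE, 5)
  rec <- evaluate_prefix(w$dataset, ranked, 10, "svm_ovr_linear", cv)
  expect_equal(rec$k, 10L)
  expect_equal(unname(rowSums(rec$confusion)),
               as.vector(table(dataset_labels(w$dataset))))
  expect_equal(rec$overall_accuracy,
               sum(diag(rec$confusion)) / sum(rec$confusion))
  expect_true(abs(rec$mcc) <= 1)
  rec2 <- evaluate_prefix(w$dataset, ranked, 10, "svm_ovr_linear", cv)
  expect_identical(rec, rec2)
  expect_error(evaluate_prefix(w$dataset, ranked, 10^6), "exceeds")
})

test_that("run_ifs builds the full curve and selections obey their rules", {
  w <- tiny_world(seed = 8)
  ranked <- filter_positive_ri(
    mcfs_rank(w$dataset, mcfs_params(t = 20, m = 2, seed = 2)))
  curve <- run_ifs(w$dataset, ranked, cv = cv_spec(6, TRUE, 4),
                   step = 10, max_k = 30)
  expect_s3_class(curve, "ifs_curve")
  expect_equal(curve$k, make_prefix_sizes(min(30, nrow(ranked)), 10))
  expect_true(all(c("acc_A", "acc_B", "acc_C") %in% names(curve)))

  # selection rules on a hand-built curve
  cv_frag <- structure(
    data.frame(k = c(20L, 750L), mcc = c(0.970, 0.977),
               overall_acc = c(0.980, 0.985)),
    class = c("ifs_curve", "data.frame"))
  expect_equal(select_optimum(cv_frag)$k, 750L)
  expect_equal(select_compact(cv_frag, tol = 0.01)$k, 20L)
  expect_equal(select_compact(cv_frag, tol = 0)$k, select_optimum(cv_frag)$k)
  flat <- structure(data.frame(k = c(10L, 20L), mcc = c(0.5, 0.5)),
                    class = c("ifs_curve", "data.frame"))
  expect_equal(select_optimum(flat)$k, 10L)
  expect_equal(select_compact(flat)$k, 10L)
})

test_that("holdout evaluation refits on training and scores the test set once", {
  w <- tiny_world(seed = 10, n_informative = 8L, effect = 0.35)
  feats <- w$truth$informative_probe_ids
  rec <- evaluate_holdout(w$dataset, w$dataset, feats, "svm_ovr_linear",
                          seed = 1)
  expect_equal(rec$k, length(feats))
  expect_gte(rec$mcc, 0.95)   # resubstitution on separable planted signal

  null_ds <- permute_labels(w$dataset, 77)
  rec0 <- evaluate_holdout(w$dataset, null_ds, feats, "svm_ovr_linear",
                           seed = 1)
  expect_lt(abs(rec0$mcc), 0.35)

  expect_error(evaluate_holdout(w$dataset, subset_probes(w$dataset, feats[1]),
                                feats, "svm_ovr_linear"), "absent")
  expect_identical(rec,
                   evaluate_holdout(w$dataset, w$dataset, feats,
                                    "svm_ovr_linear", seed = 1))
})

test_that("fold models never see held-out samples (no leakage)", {
  w <- tiny_world(seed = 11)
  # spy adapter wrapping the SVM records every training matrix it is given
  seen <- list()
  svm <- get_classifier("svm_ovr_linear")
  register_classifier("spy_svm", list(
    defaults = svm$defaults,
    fit = function(x, y, params, seed) {
      seen[[length(seen) + 1]] <<- x
      svm$fit(x, y, params, seed)
    },
    predict = svm$predict))
  on.exit(rm("spy_svm", envir = methylMCFS:::.classifiers))

  # plant a recognisable extreme value on one sample/probe
  x <- unclass(w$dataset); attr(x, "labels") <- NULL
  x[3, 1] <- 0.9999
  ds <- methyl_dataset(x, dataset_labels(w$dataset))
  ranked <- data.frame(probe_id = colnames(ds), ri = rev(seq_len(ncol(ds))))
  class(ranked) <- c("mcfs_ranking", "data.frame")
  cv <- cv_spec(6, TRUE, 9)
  evaluate_prefix(ds, ranked, 5, "spy_svm", cv)
  has_outlier <- vapply(seen, function(m) any(m == 0.9999), TRUE)
  # the outlier sample is in exactly one fold's test partition, so exactly
  # one fitted model was trained without it: its scaling cannot leak
  expect_equal(sum(!has_outlier), 1)
  expect_length(seen, 6)
})
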