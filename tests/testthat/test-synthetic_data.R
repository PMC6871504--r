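# the synthetic-world generator: determinism, shapes, planted structure

test_that("generation is deterministic and structurally sound", {
  spec <- synthetic_spec(n_per_class = c(A = 10L, B = 8L, C = 12L),
                         n_probes = 150L, n_informative = 10L, seed = 5)
  w1 <- generate_dataset(spec)
  w2 <- generate_dataset(spec)
  expect_identical(unclass(w1$dataset), unclass(w2$dataset))
  expect_identical(unclass(w1$annotation), unclass(w2$annotation))
  expect_identical(unclass(w1$terms), unclass(w2$terms))
  expect_identical(w1$truth, w2$truth)

  ds <- w1$dataset
  expect_equal(dim(ds), c(30L, 150L))
  expect_true(all(ds > 0 & ds < 1))
  expect_equal(as.vector(table(dataset_labels(ds))), c(10L, 8L, 12L))
  expect_true(all(w1$truth$informative_probe_ids %in% colnames(ds)))
  # one distinct planted gene per informative probe, inside the term map
  expect_length(unique(w1$truth$planted_genes), 10)
  expect_setequal(w1$terms[[w1$truth$planted_term_id]],
                  w1$truth$planted_genes)
  expect_gte(length(w1$terms), 21)  # planted + >= 20 fillers
  # some probes unannotated, some multi-gene
  expect_gt(sum(lengths(w1$annotation) == 0), 0)
  expect_gt(sum(lengths(w1$annotation) > 1), 0)

  # files round-trip byte-identically between two writes of the same world
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic(w1, d1); write_synthetic(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("empirical class means on planted probes match the stored truth", {
  # oracle: sample means converge to the generator's stated Beta means
  w <- generate_dataset(synthetic_spec(
    n_per_class = c(A = 30L, B = 20L, C = 30L), n_probes = 500L,
    n_informative = 20L, effect = 0.25, concentration = 30, seed = 2))
  lab <- dataset_labels(w$dataset)
  emp <- sapply(levels(lab), function(cl)
    colMeans(w$dataset[lab == cl, w$truth$informative_probe_ids,
                       drop = FALSE]))
  err <- abs(emp - w$truth$class_means)
  expect_lt(mean(err), 0.02)   # se ~ 0.08/sqrt(20)
  expect_lt(max(err), 0.08)
  # planted separation is really there: mean |between-class difference|
  # of class means on informative probes is on the order of delta
  gaps <- apply(emp, 1, function(m) mean(abs(outer(m, m, "-"))[lower.tri(diag(3))]))
  expect_gt(mean(gaps), 0.25 * 0.8)
})

test_that("larger effect sizes produce larger between-class differences", {
  gap_for <- function(delta) {
    g <- sapply(1:3, function(s) {
      w <- generate_dataset(synthetic_spec(
        n_per_class = c(A = 15L, B = 12L, C = 15L), n_probes = 100L,
        n_informative = 10L, effect = delta, seed = s))
      lab <- dataset_labels(w$dataset)
      emp <- sapply(levels(lab), function(cl)
        colMeans(w$dataset[lab == cl, w$truth$informative_probe_ids,
                           drop = FALSE]))
      mean(apply(emp, 1, function(m) max(m) - min(m)))
    })
    mean(g)
  }
  gaps <- vapply(c(0.05, 0.15, 0.25), gap_for, 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("with no planted probes, per-probe class tests look null", {
  w <- generate_dataset(synthetic_spec(
    n_per_class = c(A = 15L, B = 12L, C = 15L), n_probes = 100L,
    n_informative = 0L, effect = 0.25, seed = 9))
  expect_length(w$truth$informative_probe_ids, 0)
  expect_false("TERM_PLANTED" %in% names(w$terms))
  lab <- dataset_labels(w$dataset)
  pvals <- apply(unclass(w$dataset), 2, function(v)
    stats::kruskal.test(v, lab)$p.value)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_lte(mean(pvals < 0.05), 0.12)
})

test_that("label permutation preserves counts and destroys separation", {
  w <- tiny_world(seed = 4)
  p1 <- permute_labels(w$dataset, seed = 1)
  expect_identical(table(dataset_labels(p1)), table(dataset_labels(w$dataset)))
  strip <- function(d) { m <- unclass(d); attr(m, "labels") <- NULL; m }
  expect_identical(strip(p1), strip(w$dataset))
  expect_identical(dataset_labels(permute_labels(w$dataset, seed = 1)),
                   dataset_labels(p1))

  gap <- function(ds) {
    lab <- dataset_labels(ds)
    emp <- sapply(levels(lab), function(cl)
      colMeans(ds[lab == cl, w$truth$informative_probe_ids, drop = FALSE]))
    mean(apply(emp, 1, function(m) max(m) - min(m)))
  }
  observed <- gap(w$dataset)
  null_gaps <- vapply(1:20, function(s) gap(permute_labels(w$dataset, s)), 0)
  expect_lt(mean(null_gaps), observed / 2)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(effect = 0), "effect")
  expect_error(synthetic_spec(effect = 0.7), "effect")
  expect_error(synthetic_spec(n_probes = 10, n_informative = 10),
               "n_informative")
  expect_error(synthetic_spec(concentration = -1), "concentration")
  expect_error(synthetic_spec(n_per_class = c(10, 10)), "named")
  expect_error(synthetic_spec(n_informative = 5, planted_term_size = 3),
               "planted_term_size")
})
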