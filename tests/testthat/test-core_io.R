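# readers, writers and validation of the on-disk formats

test_that("beta matrix round-trips in both orientations and validates", {
  ds <- make_beta_dataset(c(A = 2L, B = 1L), p = 3L, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")

  write_beta_matrix(ds, f1, orientation = "probes")
  back <- read_beta_matrix(f1, orientation = "probes")
  expect_equal(dim(back), dim(ds))
  expect_equal(unclass(back), unclass(ds), tolerance = 1e-6,
               ignore_attr = TRUE)

  write_beta_matrix(ds, f2, orientation = "samples")
  back2 <- read_beta_matrix(f2, orientation = "samples")
  expect_equal(unclass(back)[, colnames(ds)], unclass(back2)[, colnames(ds)],
               ignore_attr = TRUE)

  # hand-written 3-probe x 2-sample file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "cgA\t0.1\t0.9", "cgB\t0.5\t0.4",
               "cgC\t0.2\t0.3"), f3)
  d3 <- read_beta_matrix(f3)
  expect_equal(dim(d3), c(2L, 3L))
  expect_equal(d3["s2", "cgB"], 0.4, ignore_attr = TRUE)

  # validation failures name the offender
  writeLines(c("probe_id\ts1\ts2", "cgA\t0.1\tNA"), f3)
  expect_error(read_beta_matrix(f3), "cgA.*s2")
  writeLines(c("probe_id\ts1\ts2", "cgA\t0.1\t1.7"), f3)
  expect_error(read_beta_matrix(f3), "cgA")
  writeLines(c("probe_id\ts1\ts2", "cgA\t0.1\t0.2", "cgA\t0.3\t0.4"), f3)
  expect_error(read_beta_matrix(f3), "duplicate")
  writeLines(c("probe_id\ts1\ts2", "cgA\t0.1"), f3)
  expect_error(read_beta_matrix(f3), "ragged row")

  # drop-incomplete-probes removes instead of failing
  writeLines(c("probe_id\ts1\ts2", "cgA\t0.1\tNA", "cgB\t0.5\t0.4"), f3)
  expect_warning(d <- read_beta_matrix(f3, drop_incomplete_probes = TRUE),
                 "dropping 1 probe")
  expect_equal(colnames(d), "cgB")
})

test_that("label files attach, warn on extras, and error on missing", {
  ds <- make_beta_dataset(c(A = 2L, B = 2L), p = 3L)
  f <- withr::local_tempfile(fileext = ".tsv")

  lab <- stats::setNames(c("x", "x", "y", "y"), rownames(ds))
  write_labels(lab, f)
  got <- read_labels(f)
  expect_identical(got, lab)
  ds2 <- attach_labels(ds, got)
  expect_equal(as.character(dataset_labels(ds2)), unname(lab))

  expect_warning(attach_labels(ds, c(lab, ghost = "x")), "unknown sample")
  expect_error(attach_labels(ds, lab[-1]), "no label for sample")
  expect_error(attach_labels(ds, stats::setNames(rep("one", 4), names(lab))),
               "at least 2 classes")
})

test_that("probe annotation reads the semicolon dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tgenes",
               "cg26694713\tREST;REST",   # duplicates collapse
               "cg12930304\t",            # intergenic probe
               "cg21552709\tEPHA7;REST"), f)
  ann <- read_probe_annotation(f)
  expect_equal(ann[["cg26694713"]], "REST")
  expect_length(ann[["cg12930304"]], 0)
  expect_setequal(ann[["cg21552709"]], c("EPHA7", "REST"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotation(ann, f2)
  expect_equal(unclass(read_probe_annotation(f2)), unclass(ann),
               ignore_attr = TRUE)

  writeLines(c("probe_id\tgenes", "cgX\tA", "cgX\tB"), f)
  expect_error(read_probe_annotation(f), "cgX")
  writeLines("probe_id", f)
  expect_error(read_probe_annotation(f), "columns")
})

test_that("GMT parsing, validation and round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("GO:0030182\tneuron differentiation\tREST\tEPHA7", f)
  tm <- read_gmt(f)
  expect_length(tm, 1)
  expect_setequal(tm[["GO:0030182"]], c("REST", "EPHA7"))
  expect_equal(unname(attr(tm, "term_names")["GO:0030182"]),
               "neuron differentiation")

  file.create(f2 <- withr::local_tempfile(fileext = ".gmt"))
  expect_length(read_gmt(f2), 0)

  writeLines(c("T1\tdesc\tG1\tG2", "T2\tonly-two-fields"), f)
  expect_error(read_gmt(f), "line 2")

  tm2 <- term_map(list(T1 = c("A", "B"), T2 = "C"),
                  c(T1 = "first", T2 = "second"))
  write_gmt(tm2, f)
  back <- read_gmt(f)
  expect_equal(lapply(unclass(back), sort), lapply(unclass(tm2), sort),
               ignore_attr = TRUE)
  expect_equal(attr(back, "term_names"), attr(tm2, "term_names"))

  expect_error(term_map(list(T1 = character(0))), "no genes")
})

test_that("ranked list and IFS curve writers round-trip to 6 decimals", {
  rk <- structure(data.frame(probe_id = c("cgB", "cgA"),
                             ri = c(1.2345678, 0.5),
                             stringsAsFactors = FALSE),
                  class = c("mcfs_ranking", "data.frame"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(rk, f)
  back <- read_ranked_list(f)
  expect_equal(back$probe_id, rk$probe_id)
  expect_equal(back$ri, rk$ri, tolerance = 1e-6)

  writeLines(c("rank\tprobe_id\tri", "1\tcgA\t0.1", "2\tcgB\t0.5"), f)
  expect_error(read_ranked_list(f), "non-increasing")

  curve <- structure(data.frame(k = c(10L, 20L), acc_A = c(0.9, 1),
                                acc_B = c(0.8, 0.9),
                                overall_acc = c(0.85, 0.95),
                                mcc = c(0.7123456, 0.9)),
                     class = c("ifs_curve", "data.frame"))
  write_ifs_curve(curve, f)
  back <- read_ifs_curve(f)
  expect_equal(back$k, curve$k)
  expect_equal(back$mcc, curve$mcc, tolerance = 1e-6)
})
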