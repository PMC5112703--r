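test_that("expression TSVs read and write faithfully", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1\tS2", "f1\t1.5\t2", "f2\t0\t4.25",
               "f3\t3\t1"), p)
  m <- read_expression(p, "miR")
  expect_identical(dim(m), c(3L, 2L))
  expect_identical(rownames(m), c("f1", "f2", "f3"))
  expect_equal(m["f2", "S2"], 4.25)

  # round trip preserves values
  set.seed(1)
  m2 <- expression_matrix(matrix(round(rnorm(12, 8, 2), 7), 3,
                                 dimnames = list(letters[1:3], LETTERS[1:4])),
                          "mRNA-probe")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m2, p2)
  expect_equal(unclass(read_expression(p2, "mRNA-probe")), unclass(m2),
               tolerance = 1e-6)
})

test_that("malformed expression inputs are rejected", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_expression(empty, "miR"), "empty")
  expect_error(read_expression(file.path(tempdir(), "nope.tsv"), "miR"),
               "not found")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1", "f1\tabc"), bad)
  expect_error(read_expression(bad, "miR"), "non-numeric")
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tS1", "f1\t1", "f1\t2"), dup)
  expect_warning(m <- read_expression(dup, "miR"), "duplicate")
  expect_identical(nrow(m), 2L)
})

test_that("quantile normalisation equalises column distributions", {
  m <- expression_matrix(matrix(c(1, 3, 2, 4), 2,
                                dimnames = list(c("f1", "f2"), c("A", "B"))),
                         "mRNA-probe")
  q <- quantile_normalize(m)
  expect_equal(unname(unclass(q)[, "A"]), c(1.5, 3.5))
  expect_equal(unname(unclass(q)[, "B"]), c(1.5, 3.5))

  # identical columns are a fixed point
  mm <- expression_matrix(matrix(c(5, 1, 2, 5, 1, 2), 3,
                                 dimnames = list(paste0("f", 1:3),
                                                 c("A", "B"))),
                          "mRNA-probe")
  expect_equal(unclass(quantile_normalize(mm)), unclass(mm))

  # definitional property: sorted column values identical across samples
  set.seed(3)
  big <- expression_matrix(matrix(rnorm(200, 8, 3), 20,
                                  dimnames = list(paste0("f", 1:20),
                                                  paste0("S", 1:10))),
                           "mRNA-probe")
  qb <- quantile_normalize(big)
  sorted <- apply(unclass(qb), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # ranks within each column preserved
  expect_identical(apply(unclass(qb), 2, order), apply(unclass(big), 2, order))
  expect_warning(quantile_normalize(big[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("log2 transform applies the offset convention", {
  m <- expression_matrix(matrix(c(0, 7, 1, 3), 2,
                                dimnames = list(c("f1", "f2"), c("A", "B"))),
                         "miR")
  t1 <- log2_transform(m, offset = 1)
  expect_equal(unclass(t1)["f1", "A"], 0)
  expect_equal(unclass(t1)["f2", "A"], 3)  # log2(7 + 1)
  # monotone in the input
  expect_true(all(diff(unclass(t1)[order(unclass(m))]) >= 0))
  expect_error(log2_transform(m, offset = 0), "> 0")
})

test_that("feature filtering applies both rules with hand-derived cutoffs", {
  m <- make_filter_fixture()
  res <- suppressMessages(filter_features(m))
  exp <- filter_fixture_expected
  expect_identical(sort(rownames(res$matrix)), sort(exp$retained))
  rep <- res$report
  expect_identical(rep$n_input, 20L)
  expect_identical(rep$n_dropped_abundance, exp$n_dropped_abundance)
  expect_identical(rep$n_dropped_range, exp$n_dropped_range)
  expect_identical(rep$n_retained, 7L)
  # counts reconcile
  expect_identical(rep$n_input,
                   rep$n_dropped_abundance + rep$n_dropped_range +
                     rep$n_retained)
  expect_equal(rep$thresholds_used$abundance, exp$abundance_threshold)
  expect_equal(rep$thresholds_used$range, exp$range_threshold)
  expect_identical(rep$thresholds_used$min_samples_above,
                   exp$min_samples_above)
  # a feature with 13 of 57 samples above the pooled 10th percentile is
  # dropped by the abundance rule even though its range is large
  expect_false("l1" %in% rownames(res$matrix))
  expect_false("z1" %in% rownames(res$matrix))
})

test_that("re-filtering with the recorded thresholds drops nothing", {
  m <- make_filter_fixture()
  res <- suppressMessages(filter_features(m))
  again <- suppressMessages(
    filter_features(res$matrix, thresholds = res$report$thresholds_used))
  expect_identical(rownames(again$matrix), rownames(res$matrix))
  expect_identical(again$report$n_retained, res$report$n_retained)
})

test_that("the mRNA range rule uses a fraction of the global range", {
  vals <- rbind(wide = c(rep(0, 28), rep(10, 29)),
                narrow = c(rep(5, 28), rep(5.5, 29)))
  colnames(vals) <- sprintf("S%02d", 1:57)
  m <- expression_matrix(vals, "mRNA-probe")
  res <- suppressMessages(filter_features(m))
  # global range 10, threshold 1; 'narrow' spans only 0.5
  expect_identical(rownames(res$matrix), "wide")
  expect_equal(res$report$thresholds_used$range, 1)
})

test_that("all features dropped is an error", {
  vals <- matrix(5, 3, 57, dimnames = list(paste0("f", 1:3),
                                           sprintf("S%02d", 1:57)))
  expect_error(suppressMessages(filter_features(expression_matrix(vals, "miR"))),
               "all 3 features dropped")
})

test_that("cohort samples are matched by exact barcode", {
  mk <- function(bcs, prefix) {
    df <- data.frame(barcode = bcs, check.names = FALSE)
    df[[paste0(prefix, "1")]] <- seq_along(bcs)
    df[[paste0(prefix, "2")]] <- seq_along(bcs) * 2
    df
  }
  mir <- mk(c("B1", "B2", "B3", "B4", "B5"), "m")
  mrna <- mk(c("B3", "B4", "B5", "B6", "B7"), "g")
  res <- suppressMessages(match_cohort_samples(mir, mrna))
  expect_identical(colnames(res$mir), c("B3", "B4", "B5"))
  expect_identical(colnames(res$mir), colnames(res$mrna))
  expect_equal(unname(unclass(res$mir)["m1", ]), c(3, 4, 5))
  expect_error(suppressMessages(match_cohort_samples(mk("B1", "m"),
                                                     mk("B9", "g"))),
               "no shared barcodes")
})

test_that("a patient with two samples keeps both distinct samples", {
  co <- simulate_cohort(small_sim_config())
  res <- suppressMessages(match_cohort_samples(co$mir_table, co$mrna_table))
  patients <- sub("-[0-9]+$", "", colnames(res$mir))
  expect_true(any(duplicated(patients)))
  expect_false(any(duplicated(colnames(res$mir))))
})
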