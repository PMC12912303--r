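test_that("label_hierarchy validates structure", {
  h <- label_hierarchy(c("A", "A1", "A1a"), 1:3, c(NA, "A", "A1"))
  expect_s3_class(h, "label_hierarchy")
  expect_identical(ancestors(h, "A1a"), c("A1", "A"))
  expect_error(label_hierarchy(c("A", "B"), c(1, 1), c(NA, "A")),
               "no parent")
  expect_error(label_hierarchy(c("A", "C"), c(1, 3), c(NA, "A")),
               "one level above")
  expect_error(label_hierarchy(c("A", "B"), c(1, 2), c(NA, "Z")),
               "unknown parent")
})

test_that("filter_rare_labels applies the positive-count threshold", {
  set.seed(1)
  V <- cbind(x = rep(1:0, c(60, 40)), y = rep(1:0, c(51, 49)),
             z = rep(1:0, c(49, 51)))
  ann <- annotation_matrix(V)
  h <- label_hierarchy(c("x", "y", "z"), c(1, 1, 1), c(NA, NA, NA))
  out <- filter_rare_labels(ann, h, min_positives = 50)
  expect_identical(colnames(out$annotations$values), c("x", "y"))
  expect_identical(out$hierarchy$label, c("x", "y"))
  expect_error(filter_rare_labels(ann, h, min_positives = 0), "min_positives")
  # identity case: everything above threshold 1 is retained untouched
  toy <- toy_annotations()
  ht <- label_hierarchy(c("A", "B", "C"), c(1, 2, 2), c(NA, "A", "A"))
  kept <- filter_rare_labels(toy, ht, min_positives = 1)
  expect_identical(kept$annotations$values, toy$values)
  expect_identical(kept$hierarchy$label, ht$label)
  # removing every label is an explicit failure naming the threshold
  expect_error(filter_rare_labels(toy, ht, min_positives = 1000), "1000")
})

test_that("a removed parent orphans its children into subtree roots", {
  V <- cbind(p = c(1, 1, 0, 0), c1 = c(1, 1, 1, 1), c2 = c(0, 1, 1, 1))
  ann <- annotation_matrix(V)
  h <- label_hierarchy(c("p", "c1", "c2"), c(1, 2, 2), c(NA, "p", "p"))
  out <- filter_rare_labels(ann, h, min_positives = 3)
  expect_false("p" %in% out$hierarchy$label)
  expect_true(all(is.na(out$hierarchy$parent)))
})

test_that("correlation matrices follow the exact integer definitions", {
  cs <- build_correlation_set(toy_annotations())
  expect_equal(cs$R["A", "B"], 1)
  expect_equal(cs$R["B", "A"], 0.5)
  expect_equal(cs$R["B", "C"], 0)
  expect_equal(cs$R_MS["A", "B"], 1)
  expect_equal(cs$R_ME["B", "C"], 1)
  expect_equal(cs$R_ME["C", "B"], 1)
  expect_equal(diag(cs$R), c(A = 1, B = 1, C = 1))
  expect_equal(diag(cs$R_ME), c(A = 0, B = 0, C = 0))
  expect_equal(diag(cs$R_MS), c(A = 0, B = 0, C = 0))
  # single always-positive label
  one <- annotation_matrix(matrix(1, 5, 1, dimnames = list(NULL, "A")))
  cs1 <- build_correlation_set(one)
  expect_equal(unname(cs1$R), matrix(1))
  expect_equal(unname(cs1$R_ME), matrix(0))
  expect_equal(unname(cs1$R_MS), matrix(0))
  # zero-positive labels are rejected with a pointer to the filter
  V <- cbind(a = c(1, 1), b = c(0, 0))
  expect_error(build_correlation_set(annotation_matrix(V)),
               "filter_rare_labels")
})

test_that("correlation matrices match the brute-force oracle", {
  for (seed in 1:5) {
    ann <- random_annotations(sample(10:30, 1), sample(4:8, 1), seed = seed)
    cs <- build_correlation_set(ann)
    bf <- brute_correlations(ann$values)
    expect_equal(cs$R, bf$R, tolerance = 1e-12)
    expect_equal(cs$R_ME, bf$R_ME)
    expect_equal(cs$R_MS, bf$R_MS)
  }
})

test_that("R_ME is symmetric and disjoint from R_MS", {
  for (seed in 6:15) {
    ann <- random_annotations(20, 6, seed = seed)
    cs <- build_correlation_set(ann)
    expect_identical(cs$R_ME, t(cs$R_ME))
    expect_true(all(cs$R_ME * cs$R_MS == 0))
  }
})

test_that("complete ancestor chains are recovered as symbiotic pairs", {
  fx <- hier_fixture(n = 600, seed = 9)
  h <- fx$tree$hierarchy
  for (j in h$label) {
    for (a in ancestors(h, j)) {
      expect_equal(fx$cs$R_MS[a, j], 1,
                   info = paste(a, "should be symbiotic ancestor of", j))
    }
  }
})

test_that("exclusive coverage diagnostics and the artificial other class", {
  cs <- build_correlation_set(toy_annotations())
  expect_identical(validate_exclusive_coverage(cs), "A")
  # two labels that never co-occur cover each other
  V <- cbind(a = c(1, 0, 1), b = c(0, 1, 0))
  cs2 <- build_correlation_set(annotation_matrix(V))
  expect_length(validate_exclusive_coverage(cs2), 0)
  aug <- add_other_class(cs)
  expect_length(validate_exclusive_coverage(aug), 0)
  expect_equal(unname(aug$R_ME["other", ]), c(1, 1, 1, 0))
  expect_identical(t(aug$R_ME), aug$R_ME)
  expect_error(add_other_class(aug), "already present")
})

test_that("annotation and correlation files round-trip", {
  td <- withr::local_tempdir()
  # sparse layout
  df <- data.frame(record_id = 1:4, labels = c("A;B", "A;B", "A;C", "A;C"))
  p1 <- file.path(td, "sparse.csv")
  write.csv(df, p1, row.names = FALSE)
  ann <- read_annotations(p1)
  expect_equal(unname(ann$values), unname(toy_annotations()$values))
  # dense layout
  p2 <- file.path(td, "dense.csv")
  write.csv(data.frame(record_id = 1:4, toy_annotations()$values), p2,
            row.names = FALSE)
  expect_equal(read_annotations(p2)$N_i, toy_annotations()$N_i)
  # correlation set
  cs <- build_correlation_set(ann)
  write_correlation_set(cs, file.path(td, "corr"))
  cs2 <- read_correlation_set(file.path(td, "corr"))
  expect_equal(cs2$R, cs$R)
  expect_equal(cs2$R_ME, cs$R_ME)
  expect_equal(cs2$R_MS, cs$R_MS)
  # hierarchy CSV and JSON
  h <- label_hierarchy(c("A", "B", "C"), c(1, 2, 2), c(NA, "A", "A"))
  pc <- file.path(td, "h.csv")
  write.csv(as.data.frame(h), pc, row.names = FALSE)
  expect_equal(read_hierarchy(pc)$parent, h$parent)
})
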