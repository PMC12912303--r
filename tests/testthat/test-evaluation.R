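test_that("AUROC and AUPRC match hand-worked examples", {
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 0, 1)), 0.5)
  expect_equal(auprc(c(0.9, 0.8, 0.1), c(1, 0, 1)), (1 + 2 / 3) / 2)
  # degenerate vectors are an undefined-metric signal
  expect_true(is.na(auroc(c(0.1, 0.2), c(1, 1))))
  expect_true(is.na(auprc(c(0.1, 0.2), c(0, 0))))
  expect_error(auroc(1:3, 1), "mismatch")
})

test_that("ranking metrics equal brute-force pair/rank oracles", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(20:100, 1)
    scores <- round(runif(n), 2)       # duplicated scores exercise ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(auroc(scores, labels), brute_auroc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auprc(scores, labels), brute_auprc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("macro AUPRC is 1 for perfect scores and skips undefined labels", {
  Y <- cbind(a = c(1, 0, 1, 0), b = c(0, 1, 1, 0), c = c(0, 0, 0, 0))
  m <- macro_auprc(Y, Y)
  expect_equal(as.numeric(m), 1)
  expect_equal(attr(m, "n_undefined"), 1L)
})

test_that("break-even thresholding favours sensitivity on ties", {
  # separable: midpoint of the separating gap
  expect_equal(break_even_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)),
               0.5)
  # the enumerated 4-score case: any threshold in (0.7, 0.8] balances
  t4 <- break_even_threshold(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
  expect_gt(t4, 0.7); expect_lte(t4, 0.8)
  pred <- c(0.9, 0.8, 0.7, 0.1) >= t4
  expect_equal(sum(pred & c(1, 1, 0, 0) == 1) / sum(pred), 1)
  # all scores equal: just below the score, predicting everything positive
  te <- break_even_threshold(rep(0.4, 5), c(1, 0, 1, 0, 0))
  expect_lt(te, 0.4)
  expect_true(all(rep(0.4, 5) >= te))
  expect_true(is.na(break_even_threshold(c(0.3, 0.7), c(0, 0))))
})

test_that("confusion metrics work label-wise and exam-wise", {
  truth <- rbind(c(1, 0, 1, 0), c(0, 0, 1, 1))
  colnames(truth) <- paste0("l", 1:4)
  pred <- rbind(c(1, 1, 1, 0), c(0, 0, 0, 1))
  rep <- confusion_metrics(pred, truth)
  expect_equal(rep$exam$TP, 1.5)
  expect_equal(rep$exam$FP, 0.5)
  expect_equal(rep$exam$FN, 0.5)
  expect_equal(rep$exam$TN, 1.5)
  expect_equal(rep$exam$f1, 0.75)
  # per-record counts always sum to the label count
  expect_equal(rep$exam$TP + rep$exam$TN + rep$exam$FP + rep$exam$FN, 4)
  # identity and inversion
  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$macro$sensitivity, 1)
  expect_equal(perfect$macro$specificity, 1)
  expect_equal(perfect$macro$f1, 1)
  flipped <- confusion_metrics(1 - truth, truth)
  expect_equal(flipped$macro$sensitivity, 0)
  expect_equal(flipped$macro$specificity, 0)
  expect_error(confusion_metrics(pred[, 1:3], truth), "shape")
})

test_that("consistency rates match a brute-force per-record check", {
  fx <- hier_fixture(n = 200, seed = 23)
  # copies of chain-complete, exclusivity-respecting truth are consistent
  truth <- fx$ann$values
  r0 <- consistency_report(truth, rep(0.5, ncol(truth)), fx$cs)
  expect_equal(r0$exclusive_violation_rate, 0)
  expect_equal(r0$broken_chain_rate, 0)
  # a record predicting both members of an exclusive pair violates
  pair <- which(fx$cs$R_ME == 1, arr.ind = TRUE)[1, ]
  bad <- truth
  bad[1, ] <- 0; bad[1, c(pair[1], pair[2])] <- 1
  r1 <- consistency_report(bad, rep(0.5, ncol(bad)), fx$cs)
  expect_gte(r1$exclusive_violation_rate, 1 / nrow(bad))
  # random predictions against the naive double loop
  set.seed(24)
  for (rep in 1:4) {
    P <- matrix(rbinom(50 * ncol(truth), 1, 0.3), 50, ncol(truth))
    got <- consistency_report(P, rep(0.5, ncol(P)), fx$cs)
    want <- brute_consistency(P, fx$cs$R_ME, fx$cs$R_MS)
    expect_equal(got$exclusive_violation_rate,
                 unname(want["exclusive_violation_rate"]))
    expect_equal(got$broken_chain_rate,
                 unname(want["broken_chain_rate"]))
  }
})

test_that("Bland-Altman agreement has the closed-form limits", {
  same <- bland_altman(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5))
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(same$loa), c(0, 0))
  ba <- bland_altman(c(0.6, 0.4), c(0.5, 0.5))
  expect_equal(ba$mean_diff, 0)
  expect_equal(unname(ba$loa), c(-1, 1) * 1.96 * sd(c(0.1, -0.1)),
               tolerance = 1e-12)
  expect_equal(ba$max_abs_diff, 0.1)
  # shifting one arm by a constant shifts the mean difference exactly
  a <- runif(6); b <- runif(6)
  expect_equal(bland_altman(a, b + 0.2)$mean_diff,
               bland_altman(a, b)$mean_diff - 0.2, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "length")
})

test_that("paired t-test matches the t distribution and its symmetries", {
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, sqrt(3) * 2, tolerance = 1e-4)
  expect_equal(r$p, 2 * pt(-sqrt(3) * 2, df = 2), tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_warning(z <- paired_t_test(c(1, 2), c(1, 2)), "zero-variance")
  expect_true(is.na(z$t))
  a <- c(0.5, 0.62, 0.48, 0.7); b <- c(0.52, 0.58, 0.5, 0.6)
  fwd <- paired_t_test(a, b); rev <- paired_t_test(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
})

test_that("the full metric report mirrors the label-wise table layout", {
  set.seed(26)
  n <- 80
  Y <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.2))
  S <- Y * 0.6 + matrix(runif(2 * n, 0, 0.4), n)
  rep <- metric_report(S, Y)
  expect_identical(names(rep$label),
                   c("label", "AUROC", "AUPRC", "TP", "TN", "FP", "FN",
                     "Sen", "Spe", "F1", "Acc"))
  expect_true(all(rep$label$AUROC > 0.9))
  td <- withr::local_tempdir()
  write_metric_report(rep, file.path(td, "report"))
  expect_true(file.exists(file.path(td, "report.csv")))
  back <- read.csv(file.path(td, "report.csv"))
  expect_equal(back$AUPRC, rep$label$AUPRC, tolerance = 1e-9)
})
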