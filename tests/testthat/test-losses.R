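test_that("sigmoid activation maps logits to clamped probabilities", {
  expect_equal(sigmoid_act(0), 0.5)
  expect_equal(sigmoid_act(c(1, -1)), c(0.7310586, 0.2689414),
               tolerance = 1e-6)
  expect_equal(sigmoid_act(1e6), 1 - 1e-7)
  expect_equal(sigmoid_act(-1e6), 1e-7)
})

test_that("concurrent softmax follows the attenuated-suppression formula", {
  excl <- build_correlation_set(annotation_matrix(
    cbind(a = c(1, 0, 1), b = c(0, 1, 0))))
  # fully exclusive pair reduces to plain softmax at any tau
  for (tau in c(1, 3, 17))
    expect_equal(concurrent_softmax(c(0, 0), excl, tau), c(0.5, 0.5),
                 ignore_attr = TRUE)
  # r = 0.5 both ways: direct evaluation at tau = 1 and tau = 3
  cs <- excl
  cs$R <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = dimnames(cs$R))
  expect_equal(concurrent_softmax(c(0, 0), cs, tau = 1)[1], 1 / 1.5,
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(concurrent_softmax(c(0, 0), cs, tau = 3)[1], 1 / 1.125,
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_error(concurrent_softmax(c(0, 0), cs, tau = 0.5), "tau")
  # tau = Inf delegates to local softmax
  expect_equal(concurrent_softmax(c(0.4, -1), excl, tau = Inf),
               local_softmax(c(0.4, -1), excl))
})

test_that("concurrent softmax is monotone in tau and converges to local softmax", {
  set.seed(31)
  ann <- random_annotations(40, 6, seed = 31)
  cs <- build_correlation_set(ann)
  z <- rnorm(6)
  taus <- c(1, 2, 4, 8, 16, 64)
  sig <- sapply(taus, function(tau) concurrent_softmax(z, cs, tau))
  expect_true(all(diff(t(sig)) >= -1e-12))  # non-decreasing in tau
  ls <- local_softmax(z, cs, warn = FALSE)
  gaps <- sapply(taus, function(tau)
    max(abs(concurrent_softmax(z, cs, tau) - ls)))
  expect_true(all(diff(gaps) <= 1e-12))     # gap shrinks with tau
  # residual suppression (1 - r)^tau bounds the gap; at tau = 640 any
  # nonzero r >= 0.1 leaves less than 1e-6
  r_nonzero <- cs$R[cs$R > 0 & cs$R < 1]
  if (length(r_nonzero) && min(r_nonzero) >= 0.1)
    expect_lt(max(abs(concurrent_softmax(z, cs, 640) - ls)), 1e-6)
})

test_that("local softmax normalizes only over exclusive partners", {
  reset_coverage_warning()
  # all pairs exclusive: identical to softmax
  V <- diag(3); colnames(V) <- c("a", "b", "c")
  cs <- build_correlation_set(annotation_matrix(rbind(V, V)))
  expect_equal(local_softmax(c(1, 1, 1), cs), rep(1 / 3, 3),
               ignore_attr = TRUE, tolerance = 1e-9)
  # toy hierarchy: only B and C exclusive; A saturates with a warning
  toy <- build_correlation_set(toy_annotations())
  expect_warning(s <- local_softmax(c(2, 1, 1), toy), "saturate")
  expect_equal(unname(s["B"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(s["A"]), 1 - 1e-7)
  # warning fires once per session only
  expect_silent(local_softmax(c(2, 1, 1), toy))
  # shift invariance
  z <- c(0.3, -1.2, 0.8)
  expect_equal(local_softmax(z, toy, warn = FALSE),
               local_softmax(z + 5, toy, warn = FALSE), tolerance = 1e-9)
})

test_that("local softmax output moves with its own and its rivals' logits", {
  V <- diag(3); colnames(V) <- c("a", "b", "c")
  cs <- build_correlation_set(annotation_matrix(rbind(V, V)))
  z <- c(0, 0.5, -0.5)
  s0 <- local_softmax(z, cs)
  up <- local_softmax(z + c(0.3, 0, 0), cs)
  expect_gt(up[1], s0[1])
  expect_lt(up[2], s0[2])
  expect_lt(up[3], s0[3])
})

test_that("symbiotic ranking regularizer has the right limits and values", {
  toy <- build_correlation_set(toy_annotations())     # pairs A->B, A->C
  none <- toy; none$R_MS[] <- 0
  expect_equal(srr(c(0.5, 0.5, 0.5), none), 0)
  # equal activations: every pair contributes exp(0); here P = 2
  expect_equal(srr(c(0.5, 0.5, 0.5), toy), log(3))
  three <- toy
  three$R_MS[] <- 0; three$R_MS[1, 2] <- three$R_MS[1, 3] <- three$R_MS[2, 3] <- 1
  expect_equal(srr(c(0.2, 0.2, 0.2), three), log(4), tolerance = 1e-9)
  # single pair, parent 0.9 over child 0.1
  one <- toy; one$R_MS[] <- 0; one$R_MS[1, 2] <- 1
  expect_equal(srr(c(0.9, 0.1, 0), one), log(1 + exp(-0.8)),
               tolerance = 1e-9)
  # increasing the child-over-parent margin increases the penalty
  expect_gt(srr(c(0.1, 0.9, 0), one), srr(c(0.2, 0.8, 0), one))
})

test_that("weighted BCE matches hand evaluation", {
  expect_equal(weighted_bce(1, 0.5, 1), -log(0.5))
  expect_equal(weighted_bce(c(1, 0), c(0.8, 0.4), c(1, 2)),
               -(log(0.8) + 2 * log(0.6)) / 2, tolerance = 1e-9)
  # perfect predictions at the clamp bound stay below the clamp limit
  expect_lt(weighted_bce(c(1, 0), c(1, 0), c(3, 3)), 2 * 3 * -log(1 - 1e-7))
  expect_error(weighted_bce(c(1, 0), 0.5), "mismatch")
})

test_that("class priors match the stated formulas and permutation", {
  pr <- compute_priors(N = 100, N_i = c(a = 50, b = 30, c = 20))
  expect_equal(pr$v1, c(a = 0, b = log(7 / 3), c = log(4)), tolerance = 1e-6)
  expect_equal(unname(pr$v2), unname(rev(pr$v1)))
  expect_equal(pr$pi1, log(c(a = 0.5, b = 0.3, c = 0.2)), tolerance = 1e-9)
  expect_equal(unname(pr$pi2), unname(rev(pr$pi1)))
  expect_equal(pr$w, c(a = 2, b = 100 / 30, c = 5))
  # equal counts: the permuted priors coincide with the originals
  pr2 <- compute_priors(N = 90, N_i = c(x = 30, y = 30, z = 30))
  expect_equal(pr2$v2, pr2$v1)
  expect_equal(pr2$pi2, pr2$pi1)
  expect_error(compute_priors(N = 10, N_i = c(ok = 5, allpos = 10)),
               "allpos")
  expect_error(compute_priors(N = 10, N_i = c(ok = 5, none = 0)), "none")
})

test_that("the inverse-order permutation is an involution for distinct counts", {
  set.seed(77)
  for (rep in 1:10) {
    N_i <- sample(1000, 9)
    v <- rnorm(9)
    expect_equal(inversed(inversed(v, N_i), N_i), v)
  }
})

test_that("logit adjustments recover the class priors at zero logit", {
  pr <- compute_priors(N = 100, N_i = c(a = 50, b = 30, c = 20))
  cs <- build_correlation_set(toy_annotations())
  bal <- adjusted_activation(c(0, 0, 0), expert_spec("sigmoid", "balanced"),
                             pr, cs)
  expect_equal(unname(bal), c(0.5, 0.3, 0.2), tolerance = 1e-9)
  # long-tailed variant is the unadjusted activation
  z <- c(0.2, -0.4, 1)
  expect_equal(adjusted_activation(z, expert_spec("sigmoid", "longtailed"), pr, cs),
               sigmoid_act(z), ignore_attr = TRUE)
  # inverse sigmoid at z = 0 reverses the prior spectrum across labels
  inv <- adjusted_activation(c(0, 0, 0), expert_spec("sigmoid", "inverse"),
                             pr, cs)
  expect_equal(unname(inv), c(0.8, 0.5, 0.2), tolerance = 1e-9)
})

test_that("expert losses compose BCE and the regularizer as specified", {
  fx <- hier_fixture(n = 300, seed = 13)
  C <- length(fx$priors$N_i)
  set.seed(101)
  z <- rnorm(C); y <- fx$ann$values[7, ]
  # srr_weight = 0 turns a symbiotic expert into its plain counterpart
  expect_equal(
    expert_loss(y, z, expert_spec("symbiotic_sigmoid", "balanced",
                                  srr_weight = 0), fx$priors, fx$cs),
    expert_loss(y, z, expert_spec("sigmoid", "balanced"), fx$priors, fx$cs))
  # all-zero R_MS likewise
  cs0 <- fx$cs; cs0$R_MS[] <- 0
  expect_equal(
    expert_loss(y, z, expert_spec("symbiotic_sigmoid", "balanced"),
                fx$priors, cs0),
    expert_loss(y, z, expert_spec("sigmoid", "balanced"), fx$priors, cs0))
  # symbiotic loss = plain + weight * srr of the same activation
  spec <- expert_spec("symbiotic_local_softmax", "inverse", srr_weight = 0.7)
  sig <- adjusted_activation(z, spec, fx$priors, fx$cs)
  expect_equal(
    expert_loss(y, z, spec, fx$priors, fx$cs),
    expert_loss(y, z, expert_spec("local_softmax", "inverse"),
                fx$priors, fx$cs) + 0.7 * srr(sig, fx$cs),
    tolerance = 1e-12)
})

test_that("the twelve-expert grid sums additively", {
  fx <- hier_fixture(n = 300, seed = 17)
  C <- length(fx$priors$N_i)
  set.seed(55)
  Z <- matrix(rnorm(C * 12), C, 12)
  y <- fx$ann$values[3, ]
  specs <- expert_grid()
  expect_length(specs, 12)
  expect_identical(vapply(specs, `[[`, "", "base"),
                   c(L1 = "sigmoid", L2 = "sigmoid", L3 = "sigmoid",
                     L4 = "symbiotic_sigmoid", L5 = "symbiotic_sigmoid",
                     L6 = "symbiotic_sigmoid",
                     L7 = "local_softmax", L8 = "local_softmax",
                     L9 = "local_softmax",
                     L10 = "symbiotic_local_softmax",
                     L11 = "symbiotic_local_softmax",
                     L12 = "symbiotic_local_softmax"))
  indiv <- sum(vapply(1:12, function(k)
    expert_loss(y, Z[, k], specs[[k]], fx$priors, fx$cs), numeric(1)))
  expect_equal(total_loss(y, Z, fx$priors, fx$cs), indiv, tolerance = 1e-10)
})

test_that("analytic loss gradients match central finite differences", {
  fx <- hier_fixture(n = 300, seed = 19)
  C <- length(fx$priors$N_i)
  specs <- expert_grid()
  set.seed(7)
  for (rep in 1:5) {
    z <- runif(C, -3, 3)
    y <- fx$ann$values[sample(fx$ann$N, 1), ]
    for (spec in specs) {
      g <- expert_loss_grad(y, z, spec, fx$priors, fx$cs)
      fd <- central_diff_grad(function(zz)
        expert_loss(y, zz, spec, fx$priors, fx$cs), z)
      expect_lt(max(abs(g - fd)) / max(1, max(abs(fd))), 1e-6)
    }
  }
})
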