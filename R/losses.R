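#' @useDynLib ecgexperts, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.clamp <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

.ecg_env <- new.env(parent = emptyenv())

#' Sigmoid activation
#'
#' Element-wise logistic map of raw logits to (0, 1), clamped to
#' `[eps, 1 - eps]` so that downstream logarithms stay finite.
#'
#' @param z numeric vector of logits.
#' @param eps clamp bound.
#' @return Numeric vector in `[eps, 1 - eps]`.
#' @export
sigmoid_act <- function(z, eps = 1e-7) {
  .clamp(stats::plogis(z), eps)
}

# shared core: sigma_i = e^{z_i} / (sum_j s_ij e^{z_j} + e^{z_i}) for a
# suppression matrix s (zero diagonal), computed with max-subtraction
.suppressed_softmax <- function(z, S, eps) {
  e <- exp(z - max(z))
  den <- as.vector(S %*% e) + e
  out <- .clamp(e / den, eps)
  names(out) <- if (!is.null(names(z))) names(z) else rownames(S)
  out
}

#' Concurrent softmax
#'
#' Softmax whose cross-class suppression is attenuated by the co-occurrence
#' statistics: class j suppresses class i with coefficient
#' `(1 - r_ij)^tau`, where `r_ij = N_ij / N_j` is the conditional probability
#' of i given j. At `tau = 1` this is the concurrent softmax used in
#' multi-label detection; as `tau` grows the suppression from co-occurring
#' classes fades, and `tau = Inf` leaves only the fully exclusive classes —
#' the local softmax.
#'
#' @param z numeric vector of logits, one per label.
#' @param cs a [build_correlation_set()] result over the same labels.
#' @param tau suppression sharpness, `>= 1` or `Inf`.
#' @param eps clamp bound.
#' @return Activation vector in `[eps, 1 - eps]`.
#' @export
concurrent_softmax <- function(z, cs, tau = 1, eps = 1e-7) {
  if (!(is.infinite(tau) || tau >= 1)) stop("tau must be >= 1 or Inf")
  if (is.infinite(tau)) return(local_softmax(z, cs, eps = eps))
  S <- (1 - cs$R)^tau
  diag(S) <- 0       # r_ii = 1 already zeroes the diagonal when N_i > 0
  .suppressed_softmax(z, S, eps)
}

#' Local softmax
#'
#' Softmax restricted to each label's mutually exclusive set: class i
#' competes only against the classes it can never co-occur with,
#' `sigma_i = e^{z_i} / (sum_j R_ME[i, j] e^{z_j} + e^{z_i})`. This keeps
#' softmax-style suppression of impossible co-diagnoses while leaving
#' co-occurring labels untouched. A label with no exclusive partner has an
#' empty denominator sum and saturates at `1 - eps`; this is flagged with a
#' one-time warning (the documented remedy is [add_other_class()]).
#'
#' @inheritParams concurrent_softmax
#' @param warn warn (once per session) about labels without exclusive
#'   partners.
#' @return Activation vector in `[eps, 1 - eps]`, invariant under adding a
#'   constant to all logits.
#' @export
local_softmax <- function(z, cs, eps = 1e-7, warn = TRUE) {
  uncovered <- validate_exclusive_coverage(cs)
  if (warn && length(uncovered) && !isTRUE(.ecg_env$warned_coverage)) {
    .ecg_env$warned_coverage <- TRUE
    warning("label(s) without a mutually exclusive partner saturate under ",
            "local softmax: ", paste(uncovered, collapse = ", "),
            " (consider add_other_class())", call. = FALSE)
  }
  .suppressed_softmax(z, cs$R_ME, eps)
}

#' Symbiotic ranking regularizer
#'
#' Pairwise ranking penalty enforcing that an ancestor's activation
#' dominates its descendants': `log(1 + sum_(i,j) R_MS[i,j] exp(sigma_j -
#' sigma_i))` over all symbiotic pairs (i ancestor, j descendant). Zero when
#' there are no symbiotic pairs; `log(1 + P)` when all activations are equal
#' over P pairs; grows with each child-over-parent margin.
#'
#' @param sigma activation vector in `[0, 1]`.
#' @param cs correlation set carrying `R_MS`.
#' @return Nonnegative scalar.
#' @export
srr <- function(sigma, cs) {
  idx <- which(cs$R_MS == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  log1p(sum(exp(sigma[idx[, 2]] - sigma[idx[, 1]])))
}

#' Class-weighted binary cross-entropy
#'
#' `-(1/C) sum_i w_i [y_i log(sigma_i) + (1 - y_i) log(1 - sigma_i)]`, with
#' activations clamped to `[eps, 1 - eps]` before the logarithms. The
#' conventional weights are `w_i = N / N_i` (inverse prevalence).
#'
#' @param y binary target vector.
#' @param sigma activation vector, same length.
#' @param w per-class weights; `NULL` for unweighted.
#' @param eps clamp bound.
#' @return Scalar loss.
#' @export
weighted_bce <- function(y, sigma, w = NULL, eps = 1e-7) {
  if (length(y) != length(sigma)) stop("y and sigma length mismatch")
  if (is.null(w)) w <- rep(1, length(y))
  if (length(w) != length(y)) stop("w length mismatch")
  s <- .clamp(sigma, eps)
  -mean(w * (y * log(s) + (1 - y) * log(1 - s)))
}

#' Inverse-order permutation of a prior vector
#'
#' Ranks labels by positive count `N_i` in descending order (ties broken by
#' label index, stable) and hands the rank-k label the prior of rank
#' `C - 1 - k`: the head of the long tail receives the tail's prior and vice
#' versa. Applying it twice restores the original vector when all `N_i` are
#' distinct.
#'
#' @param v prior vector.
#' @param N_i per-label positive counts defining the rank order.
#' @return Permuted vector.
#' @export
inversed <- function(v, N_i) {
  if (length(v) != length(N_i)) stop("length mismatch")
  ord <- order(-N_i)    # stable: ties keep ascending label index
  out <- v
  out[ord] <- v[rev(ord)]
  out
}

#' Class priors for the logit-adjusted loss variants
#'
#' Computes, from the annotation counts: the BCE weights `w_i = N / N_i`;
#' the balanced sigmoid prior `v1_i = log(N / N_i - 1)` and its inverse-order
#' permutation `v2`; the balanced local-softmax prior `pi1_i = log(N_i / N)`
#' and its permutation `pi2`. Subtracting `v1` from the logits simulates
#' training under a uniform class distribution; further adding `v2`
#' simulates the reversed long tail (and analogously `pi1`, `pi2` for local
#' softmax).
#'
#' @param ann an [annotation_matrix()], or `NULL` if `N` and `N_i` are given.
#' @param N total record count (when `ann` is `NULL`).
#' @param N_i per-label positive counts (when `ann` is `NULL`).
#' @return A `class_priors` list: `N`, `N_i`, `w`, `v1`, `v2`, `pi1`, `pi2`.
#' @export
compute_priors <- function(ann = NULL, N = NULL, N_i = NULL) {
  if (!is.null(ann)) {
    stopifnot(inherits(ann, "annotation_matrix"))
    N <- ann$N; N_i <- ann$N_i
  }
  bad <- N_i <= 0 | N_i >= N
  if (any(bad)) {
    nm <- if (!is.null(names(N_i))) names(N_i)[bad] else which(bad)
    stop("degenerate label(s) (N_i must satisfy 0 < N_i < N): ",
         paste(nm, collapse = ", "))
  }
  v1 <- log(N / N_i - 1)
  pi1 <- log(N_i / N)
  pr <- list(N = N, N_i = N_i, w = N / N_i,
             v1 = v1, v2 = inversed(v1, N_i),
             pi1 = pi1, pi2 = inversed(pi1, N_i))
  class(pr) <- "class_priors"
  pr
}

#' Specification of one expert loss
#'
#' An expert is one cell of the 4 x 3 grid (base activation x distribution
#' variant). Bases: plain `sigmoid`, `symbiotic_sigmoid` (sigmoid + SRR),
#' `local_softmax`, `symbiotic_local_softmax` (local softmax + SRR).
#' Variants: `longtailed` (no adjustment), `balanced`, `inverse`.
#'
#' @param base one of `"sigmoid"`, `"symbiotic_sigmoid"`, `"local_softmax"`,
#'   `"symbiotic_local_softmax"` (the internal `"softmax"` base — full
#'   softmax over all labels — is accepted for baseline comparisons).
#' @param variant one of `"longtailed"`, `"balanced"`, `"inverse"`.
#' @param srr_weight coefficient on the symbiotic ranking regularizer.
#' @param tau reserved for concurrent-softmax experiments; `Inf` means local
#'   softmax.
#' @return An `expert_spec` list.
#' @export
expert_spec <- function(base = c("sigmoid", "symbiotic_sigmoid",
                                 "local_softmax", "symbiotic_local_softmax",
                                 "softmax"),
                        variant = c("longtailed", "balanced", "inverse"),
                        srr_weight = 1, tau = Inf) {
  base <- match.arg(base)
  variant <- match.arg(variant)
  if (srr_weight < 0) stop("srr_weight must be nonnegative")
  spec <- list(base = base, variant = variant,
               srr_weight = srr_weight, tau = tau)
  class(spec) <- "expert_spec"
  spec
}

#' The twelve expert losses, in canonical order
#'
#' Experts 1-3: sigmoid (longtailed, balanced, inverse); 4-6: symbiotic
#' sigmoid; 7-9: local softmax; 10-12: symbiotic local softmax. Their sum is
#' the total training loss of the multi-expert model.
#'
#' @param srr_weight coefficient on the ranking regularizer for symbiotic
#'   experts.
#' @return List of 12 [expert_spec()] objects, named `L1`..`L12`.
#' @export
expert_grid <- function(srr_weight = 1) {
  bases <- c("sigmoid", "symbiotic_sigmoid",
             "local_softmax", "symbiotic_local_softmax")
  variants <- c("longtailed", "balanced", "inverse")
  specs <- list()
  for (b in bases) for (v in variants)
    specs[[length(specs) + 1]] <- expert_spec(b, v, srr_weight = srr_weight)
  names(specs) <- paste0("L", seq_along(specs))
  specs
}

.spec_uses_srr <- function(spec) grepl("^symbiotic_", spec$base)

.spec_family <- function(spec) {
  switch(spec$base,
         sigmoid = , symbiotic_sigmoid = "sigmoid",
         local_softmax = , symbiotic_local_softmax = "local_softmax",
         softmax = "softmax")
}

# additive logit offset implementing the distribution variant
.spec_offset <- function(spec, priors) {
  fam <- .spec_family(spec)
  if (fam == "sigmoid") {
    switch(spec$variant,
           longtailed = 0,
           balanced = -priors$v1,
           inverse = -priors$v1 + priors$v2)
  } else if (fam == "local_softmax") {
    switch(spec$variant,
           longtailed = 0,
           balanced = priors$pi1,
           inverse = priors$pi1 - priors$pi2)
  } else 0  # plain-softmax baseline takes no adjustment
}

#' Logit-adjusted activation of one expert
#'
#' Applies the expert's distribution variant as an additive logit offset and
#' then its base activation: sigmoid family `sigma(z)`, `sigma(z - v1)`,
#' `sigma(z - v1 + v2)`; local-softmax family `LS(z)`, `LS(z + pi1)`,
#' `LS(z + pi1 - pi2)`.
#'
#' @param z logit vector.
#' @param spec an [expert_spec()].
#' @param priors a [compute_priors()] result.
#' @param cs correlation set (needed by the local-softmax family).
#' @param eps clamp bound.
#' @return Activation vector.
#' @export
adjusted_activation <- function(z, spec, priors, cs, eps = 1e-7) {
  u <- z + .spec_offset(spec, priors)
  fam <- .spec_family(spec)
  if (fam == "sigmoid") return(sigmoid_act(u, eps))
  if (fam == "softmax") {
    S <- matrix(1, length(u), length(u)); diag(S) <- 0
    return(.suppressed_softmax(u, S, eps))
  }
  local_softmax(u, cs, eps = eps)
}

#' Loss of one expert on one record
#'
#' Class-weighted BCE of the expert's adjusted activation against the binary
#' target, plus `srr_weight` times the symbiotic ranking regularizer of that
#' same activation for symbiotic bases.
#'
#' @param y binary target vector.
#' @param z logit vector.
#' @param spec an [expert_spec()].
#' @param priors a [compute_priors()] result.
#' @param cs correlation set.
#' @param use_class_weights apply `w_i = N / N_i` in the BCE.
#' @param eps clamp bound.
#' @return Scalar loss.
#' @export
expert_loss <- function(y, z, spec, priors, cs,
                        use_class_weights = TRUE, eps = 1e-7) {
  sigma <- adjusted_activation(z, spec, priors, cs, eps)
  w <- if (use_class_weights) priors$w else NULL
  L <- weighted_bce(y, sigma, w, eps)
  if (.spec_uses_srr(spec) && spec$srr_weight > 0)
    L <- L + spec$srr_weight * srr(sigma, cs)
  L
}

#' Total loss over the twelve experts
#'
#' Plain sum of the twelve expert losses, each applied to its own logit
#' vector.
#'
#' @param y binary target vector.
#' @param zs list of 12 logit vectors (or a C x 12 matrix), one per expert.
#' @param priors,cs,use_class_weights,eps as in [expert_loss()].
#' @param specs expert specifications; defaults to [expert_grid()].
#' @return Scalar total loss.
#' @export
total_loss <- function(y, zs, priors, cs, specs = expert_grid(),
                       use_class_weights = TRUE, eps = 1e-7) {
  if (is.matrix(zs)) zs <- lapply(seq_len(ncol(zs)), function(k) zs[, k])
  if (length(zs) != length(specs)) stop("need one logit vector per expert")
  sum(vapply(seq_along(specs), function(k) {
    expert_loss(y, zs[[k]], specs[[k]], priors, cs, use_class_weights, eps)
  }, numeric(1)))
}

# ---- batched forward/backward used by both the gradient API and training ----

# Forward activations for a logit matrix Z (C x B) under one expert spec.
# Returns the clamped activation matrix plus what backward needs.
.act_forward <- function(Z, spec, priors, cs, eps = 1e-7) {
  off <- .spec_offset(spec, priors)
  U <- Z + off   # off recycles down columns (length C)
  fam <- .spec_family(spec)
  if (fam == "sigmoid") {
    raw <- stats::plogis(U)
    return(list(fam = "sigmoid", raw = raw, sig = .clamp(raw, eps),
                eps = eps))
  }
  S <- if (fam == "softmax") {
    M <- matrix(1, nrow(U), nrow(U)); diag(M) <- 0; M
  } else cs$R_ME
  mx <- apply(U, 2, max)
  E <- exp(sweep(U, 2, mx))
  Den <- S %*% E + E
  raw <- E / Den
  list(fam = "suppressed", raw = raw, sig = .clamp(raw, eps), eps = eps,
       S = S, E = E, Den = Den)
}

# Backward: dL/dZ from dL/dsigma (gradient w.r.t. the clamped activation).
.act_backward <- function(G, fw) {
  mask <- (fw$raw > fw$eps) & (fw$raw < 1 - fw$eps)
  G <- G * mask
  if (fw$fam == "sigmoid") return(G * fw$raw * (1 - fw$raw))
  # suppressed softmax: dL/du_k = g_k s_k (1 - s_k) - e_k * (S^T h)_k,
  # h_i = g_i s_i / Den_i  (shift-invariant because e/Den is)
  s <- fw$raw
  H <- G * s / fw$Den
  G * s * (1 - s) - fw$E * (t(fw$S) %*% H)
}

# Per-record loss and gradient for a batch: Y, Z are C x B. Loss is the mean
# over the batch of the per-record expert loss; grad is dLoss/dZ (C x B).
.expert_loss_batch <- function(Y, Z, spec, priors, cs,
                               use_class_weights = TRUE, eps = 1e-7) {
  C <- nrow(Z); B <- ncol(Z)
  w <- if (use_class_weights) priors$w else rep(1, C)
  fw <- .act_forward(Z, spec, priors, cs, eps)
  Sg <- fw$sig
  bce <- -colSums(w * (Y * log(Sg) + (1 - Y) * log(1 - Sg))) / C
  Gs <- -(w * (Y / Sg - (1 - Y) / (1 - Sg))) / C   # dBCE/dsigma
  loss <- mean(bce)
  if (.spec_uses_srr(spec) && spec$srr_weight > 0) {
    idx <- which(cs$R_MS == 1, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      Ex <- exp(Sg[idx[, 2], , drop = FALSE] - Sg[idx[, 1], , drop = FALSE])
      Ssum <- colSums(Ex)
      loss <- loss + spec$srr_weight * mean(log1p(Ssum))
      scale <- spec$srr_weight / (1 + Ssum)         # per record
      Gsrr <- matrix(0, C, B)
      for (p in seq_len(nrow(idx))) {
        contrib <- Ex[p, ] * scale
        Gsrr[idx[p, 2], ] <- Gsrr[idx[p, 2], ] + contrib
        Gsrr[idx[p, 1], ] <- Gsrr[idx[p, 1], ] - contrib
      }
      Gs <- Gs + Gsrr
    }
  }
  grad <- .act_backward(Gs, fw) / B
  list(loss = loss, grad = grad)
}

#' Analytic gradient of an expert loss with respect to the logits
#'
#' Exact derivative of [expert_loss()] (BCE through the adjusted activation,
#' plus the ranking regularizer for symbiotic bases) with respect to `z`.
#' Where the activation is clamped the gradient is zero, matching the
#' clamped forward value.
#'
#' @inheritParams expert_loss
#' @return Numeric vector, same length as `z`.
#' @export
expert_loss_grad <- function(y, z, spec, priors, cs,
                             use_class_weights = TRUE, eps = 1e-7) {
  out <- .expert_loss_batch(matrix(y, ncol = 1), matrix(z, ncol = 1),
                            spec, priors, cs, use_class_weights, eps)
  as.vector(out$grad)
}
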