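# Independent brute-force oracles and shared fixtures. These deliberately
# use naive loops / pairwise enumeration so they share no code path with the
# package implementations they check.

# correlation matrices by explicit double loop over label pairs and records
brute_correlations <- function(V) {
  C <- ncol(V)
  N_i <- colSums(V)
  R <- matrix(NA_real_, C, C, dimnames = list(colnames(V), colnames(V)))
  R_ME <- matrix(0, C, C, dimnames = dimnames(R))
  R_MS <- matrix(0, C, C, dimnames = dimnames(R))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    nij <- 0
    for (r in seq_len(nrow(V))) if (V[r, i] == 1 && V[r, j] == 1) nij <- nij + 1
    R[i, j] <- nij / N_i[j]
    if (i != j) {
      if (nij == 0) R_ME[i, j] <- 1
      if (nij == N_i[j]) R_MS[i, j] <- 1
    }
  }
  list(R = R, R_ME = R_ME, R_MS = R_MS)
}

# AUROC as an explicit positive-negative pair count (ties worth 1/2)
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# average precision by walking the ranked list one record at a time
brute_auprc <- function(scores, labels) {
  if (sum(labels) == 0) return(NA_real_)
  ord <- order(-scores)
  tp <- 0; precs <- c()
  for (k in seq_along(ord)) {
    if (labels[ord[k]] == 1) {
      tp <- tp + 1
      precs <- c(precs, tp / k)
    }
  }
  mean(precs)
}

# per-record consistency rates by explicit pair loops
brute_consistency <- function(P, R_ME, R_MS) {
  C <- ncol(P)
  excl <- 0; broken <- 0
  for (r in seq_len(nrow(P))) {
    e <- FALSE; b <- FALSE
    for (i in seq_len(C)) for (j in seq_len(C)) {
      if (P[r, i] == 1 && P[r, j] == 1 && R_ME[i, j] == 1) e <- TRUE
      if (P[r, j] == 1 && R_MS[i, j] == 1 && P[r, i] == 0) b <- TRUE
    }
    excl <- excl + e; broken <- broken + b
  }
  c(exclusive_violation_rate = excl / nrow(P),
    broken_chain_rate = broken / nrow(P))
}

central_diff_grad <- function(f, z, h = 1e-5) {
  vapply(seq_along(z), function(i) {
    zp <- z; zm <- z
    zp[i] <- z[i] + h; zm[i] <- z[i] - h
    (f(zp) - f(zm)) / (2 * h)
  }, numeric(1))
}

# the 4-record toy: A is a parent-like label always on; B and C never co-occur
toy_annotations <- function() {
  V <- rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 1), c(1, 0, 1))
  colnames(V) <- c("A", "B", "C")
  annotation_matrix(V)
}

# a random binary annotation matrix where every label has >= 1 positive
random_annotations <- function(n, C, seed, p = 0.35) {
  set.seed(seed)
  repeat {
    V <- matrix(rbinom(n * C, 1, p), n, C)
    colnames(V) <- paste0("lab", seq_len(C))
    if (all(colSums(V) > 0)) return(annotation_matrix(V))
  }
}

# small hierarchical fixture with non-trivial R_ME and R_MS for loss tests
hier_fixture <- function(n = 400, seed = 5) {
  cfg <- generator_config(n_records = n, sampling_rate = 100, duration = 1,
                          min_positives = max(3, round(n / 50)), seed = seed)
  tree <- make_label_tree(cfg)
  ann <- sample_annotations(tree, cfg)
  list(tree = tree, ann = ann, cs = build_correlation_set(ann),
       priors = compute_priors(ann), cfg = cfg)
}

reset_coverage_warning <- function() {
  assign("warned_coverage", NULL, envir = ecgexperts:::.ecg_env)
}
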