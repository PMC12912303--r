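#' Configuration of the synthetic ECG generator
#'
#' The generator emulates the structure of a hierarchical multi-label ECG
#' corpus: a deterministic 3-level label tree with designated mutually
#' exclusive sibling groups, leaf prevalences following a long-tailed power
#' decay, annotations that always form complete ancestor chains, and
#' 12-lead quasi-periodic waveforms (Gaussian-bump beats) with
#' label-conditioned modifications, slow baseline wander and white noise.
#' Default signal geometry matches the study corpus (15 s at 500 Hz);
#' test-scale runs use 5 s at 100 Hz.
#'
#' @param levels tree depth.
#' @param branching children per node at each level (length `levels`).
#' @param exclusive_parents labels whose child sibling groups are mutually
#'   exclusive; `NULL` selects the first level-1 node and its first child
#'   (a rate-class pair and a sub-type pair).
#' @param n_records number of records.
#' @param decay long-tail exponent: leaf k has prevalence
#'   `p_max * k^(-decay)`.
#' @param p_max prevalence of the most common leaf.
#' @param min_positives guaranteed minimum positive count per label
#'   (enforced by top-up sampling).
#' @param sampling_rate Hz.
#' @param duration seconds.
#' @param leads number of leads.
#' @param heart_rate base heart-rate range in bpm.
#' @param wander_amplitude,wander_freq baseline-wander sinusoid (frequency
#'   below 0.5 Hz).
#' @param noise_sd white-noise standard deviation.
#' @param signature_amplitude amplitude of each label's discriminative
#'   oscillatory component.
#' @param seed master seed; every stochastic draw derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(levels = 3, branching = c(2, 2, 2),
                             exclusive_parents = NULL,
                             n_records = 2000, decay = 1.5, p_max = 0.5,
                             min_positives = 40,
                             sampling_rate = 500, duration = 15, leads = 12,
                             heart_rate = c(60, 75),
                             wander_amplitude = 0.3, wander_freq = 0.25,
                             noise_sd = 0.15, signature_amplitude = 0.5,
                             seed = 1) {
  if (length(branching) != levels) stop("branching must have one entry per level")
  if (wander_freq >= 0.5) stop("baseline wander must stay below 0.5 Hz")
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

#' Deterministic label tree with exclusivity annotations
#'
#' Builds the hierarchy from the branching plan (no randomness) and marks
#' the designated sibling groups as mutually exclusive. Also returns the
#' design's ground-truth relation matrices used as oracles: the
#' ancestor-descendant matrix (`design_MS[i, j] = 1` iff i is a strict
#' ancestor of j) and the conflict matrix (`design_ME[i, j] = 1` iff the
#' chains of i and j cross an exclusive sibling group, so they can never
#' co-occur).
#'
#' @param cfg a [generator_config()].
#' @return A `label_tree` list: `hierarchy` ([label_hierarchy()]),
#'   `exclusive_groups` (list of label vectors), `leaves`, `design_MS`,
#'   `design_ME`.
#' @export
make_label_tree <- function(cfg) {
  labs <- character(0); lev <- integer(0); par <- character(0)
  prev <- character(0)
  for (l in seq_len(cfg$levels)) {
    if (l == 1) {
      cur <- LETTERS[seq_len(cfg$branching[1])]
      labs <- c(labs, cur); lev <- c(lev, rep(1L, length(cur)))
      par <- c(par, rep(NA_character_, length(cur)))
    } else {
      cur <- character(0)
      suffix <- if (l %% 2 == 0) as.character else function(i) letters[i]
      for (p in prev) {
        kids <- paste0(p, suffix(seq_len(cfg$branching[l])))
        labs <- c(labs, kids); lev <- c(lev, rep(l, length(kids)))
        par <- c(par, rep(p, length(kids)))
        cur <- c(cur, kids)
      }
    }
    prev <- cur
  }
  h <- label_hierarchy(labs, lev, par)
  excl_parents <- cfg$exclusive_parents
  if (is.null(excl_parents)) {
    root1 <- labs[lev == 1][1]
    child1 <- labs[!is.na(par) & par == root1][1]
    excl_parents <- c(root1, child1)
  }
  groups <- lapply(excl_parents, function(p) labs[!is.na(par) & par == p])
  names(groups) <- excl_parents
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("exclusive sibling groups must contain at least 2 labels")
  C <- length(labs)
  anc <- lapply(labs, function(x) ancestors(h, x))
  design_MS <- matrix(0, C, C, dimnames = list(labs, labs))
  for (j in seq_len(C)) design_MS[anc[[j]], labs[j]] <- 1
  chain <- lapply(seq_len(C), function(j) c(labs[j], anc[[j]]))
  design_ME <- matrix(0, C, C, dimnames = list(labs, labs))
  for (g in groups) {
    for (a in g) for (b in g) {
      if (a == b) next
      ia <- which(vapply(chain, function(ch) a %in% ch, logical(1)))
      ib <- which(vapply(chain, function(ch) b %in% ch, logical(1)))
      design_ME[ia, ib] <- 1
    }
  }
  diag(design_ME) <- 0
  tree <- list(hierarchy = h, exclusive_groups = groups,
               leaves = labs[lev == cfg$levels],
               design_MS = design_MS, design_ME = design_ME)
  class(tree) <- "label_tree"
  tree
}

# leaf-conflict matrix from the design conflict matrix
.leaf_conflicts <- function(tree) {
  tree$design_ME[tree$leaves, tree$leaves, drop = FALSE]
}

#' Sample a long-tailed annotation matrix over a label tree
#'
#' Leaf k (in tree order) is drawn with prevalence `p_max * k^(-decay)`; at
#' most one member of each exclusive conflict set is kept per record;
#' ancestors of every drawn leaf are set, so chains are complete by
#' construction. Labels falling short of `min_positives` are topped up by
#' assigning the deficient leaf to records that do not conflict with it.
#'
#' @param tree a [make_label_tree()] result.
#' @param cfg the [generator_config()].
#' @return An [annotation_matrix()] (records x all labels).
#' @export
sample_annotations <- function(tree, cfg) {
  set.seed(cfg$seed)
  h <- tree$hierarchy
  leaves <- tree$leaves
  L <- length(leaves)
  p <- cfg$p_max * seq_len(L)^(-cfg$decay)
  conf <- .leaf_conflicts(tree)
  per_group_need <- vapply(tree$exclusive_groups, length, integer(1))
  if (cfg$min_positives * max(per_group_need) > cfg$n_records)
    stop("min_positives infeasible for n_records with exclusive groups")
  anc <- lapply(leaves, function(x) ancestors(h, x))
  # sample leaf sets, respecting conflicts in prevalence order
  leafmat <- matrix(0, cfg$n_records, L, dimnames = list(NULL, leaves))
  draws <- matrix(stats::runif(cfg$n_records * L), cfg$n_records, L)
  for (r in seq_len(cfg$n_records)) {
    sel <- logical(L)
    for (k in seq_len(L)) {
      if (draws[r, k] >= p[k]) next
      if (any(sel & conf[, k] == 1)) next
      sel[k] <- TRUE
    }
    leafmat[r, sel] <- 1
  }
  # top-up: guarantee min_positives per leaf (parents inherit from leaves)
  for (pass in seq_len(20)) {
    counts <- colSums(leafmat)
    defic <- which(counts < cfg$min_positives)
    if (length(defic) == 0) break
    for (k in defic[order(counts[defic])]) {
      need <- cfg$min_positives - sum(leafmat[, k])
      if (need <= 0) next
      ok <- which(leafmat[, k] == 0 &
                    leafmat %*% conf[, k] == 0)
      if (length(ok) < need) {
        extra <- which(leafmat[, k] == 0 & leafmat %*% conf[, k] > 0)
        take2 <- sample(extra, min(need - length(ok), length(extra)))
        leafmat[take2, which(conf[, k] == 1)] <- 0
        ok <- c(ok, take2)
      }
      take <- if (length(ok) > need) sample(ok, need) else ok
      leafmat[take, k] <- 1
    }
  }
  if (any(colSums(leafmat) < cfg$min_positives))
    stop("could not satisfy min_positives; reduce it or add records")
  labs <- h$label
  V <- matrix(0, cfg$n_records, length(labs), dimnames = list(NULL, labs))
  V[, leaves] <- leafmat
  for (k in seq_len(L)) {
    pos <- leafmat[, k] == 1
    if (any(pos)) V[pos, anc[[k]]] <- 1
  }
  annotation_matrix(V)
}

# deterministic per-label waveform effects: every label carries a distinct
# oscillatory signature (frequency + lead pattern); the first exclusive
# group doubles/halves the beat rate; the second root's subtree inserts
# ectopic beats; remaining labels morph amplitude slightly.
.label_effects <- function(tree, cfg) {
  labs <- tree$hierarchy$label
  C <- length(labs)
  fmax <- min(45, 0.45 * cfg$sampling_rate)
  freq <- 2 + (seq_len(C) - 1) * (fmax - 2) / max(C - 1, 1)
  leadpat <- sapply(seq_len(C), function(l)
    0.6 + 0.4 * cos(2 * pi * (seq_len(cfg$leads) - 1) * l / cfg$leads))
  rate_factor <- rep(1, C); names(rate_factor) <- labs
  g1 <- tree$exclusive_groups[[1]]
  facs <- c(2, 0.5, 1.6, 0.7)[seq_along(g1)]
  rate_factor[g1] <- facs
  roots <- labs[tree$hierarchy$level == 1]
  ectopy <- rep(FALSE, C); names(ectopy) <- labs
  if (length(roots) >= 2) {
    r2 <- roots[2]
    sub <- labs[vapply(labs, function(x) r2 %in% c(x, ancestors(tree$hierarchy, x)),
                       logical(1))]
    ectopy[sub[seq_len(min(2, length(sub)))]] <- TRUE
  }
  amp_scale <- rep(1, C); names(amp_scale) <- labs
  amp_scale[!ectopy & rate_factor == 1] <-
    1 + 0.25 * ((seq_len(C) %% 3) - 1)[!ectopy & rate_factor == 1]
  list(freq = freq, leadpat = leadpat, rate_factor = rate_factor,
       ectopy = ectopy, amp_scale = amp_scale, labels = labs)
}

#' Synthesize one 12-lead record for a label set
#'
#' A quasi-periodic Gaussian-bump beat train at the base heart rate on all
#' leads (canonical per-lead scaling), with label-conditioned
#' modifications: rate-class labels rescale the beat interval (the
#' "tachycardic" member of the first exclusive group exactly halves it),
#' ectopy-class labels insert extra off-grid bumps, other labels scale the
#' beat amplitude — and every positive label adds its own oscillatory
#' signature (distinct frequency and lead pattern). Baseline wander (below
#' 0.5 Hz) and white noise are added last. Deterministic given
#' `(labels, cfg, record_seed)`.
#'
#' @param labels character vector of positive labels (chain-complete).
#' @param tree the [make_label_tree()] result.
#' @param cfg the [generator_config()].
#' @param record_seed per-record seed.
#' @return A `synthetic_record` list: `signal` (leads x T), `labels`,
#'   `record_seed`.
#' @export
synthesize_signal <- function(labels, tree, cfg, record_seed) {
  set.seed(record_seed)
  nsamp <- round(cfg$sampling_rate * cfg$duration)
  t <- (seq_len(nsamp) - 1) / cfg$sampling_rate
  eff <- .label_effects(tree, cfg)
  hr <- stats::runif(1, cfg$heart_rate[1], cfg$heart_rate[2])
  rf <- if (length(labels)) prod(eff$rate_factor[labels]) else 1
  interval <- 60 / (hr * rf)
  lead_amp <- 0.7 + 0.5 * abs(sin(pi * (seq_len(cfg$leads) - 0.25) / cfg$leads))
  amp <- if (length(labels)) prod(eff$amp_scale[labels]) else 1
  width <- 0.04
  beat_times <- seq(interval / 2, cfg$duration, by = interval)
  base <- rep(0, nsamp)
  for (bt in beat_times) base <- base + exp(-(t - bt)^2 / (2 * width^2))
  sig <- outer(lead_amp, amp * base)
  if (length(labels) && any(eff$ectopy[labels])) {
    ect <- rep(0, nsamp)
    for (bt in stats::runif(3, 0, cfg$duration))
      ect <- ect + 1.2 * exp(-(t - bt)^2 / (2 * (width / 2)^2))
    sig <- sig + outer(lead_amp, ect)
  }
  for (lb in labels) {
    l <- match(lb, eff$labels)
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- sig + cfg$signature_amplitude *
      outer(eff$leadpat[, l], sin(2 * pi * eff$freq[l] * t + phase))
  }
  if (cfg$wander_amplitude > 0)
    sig <- sig + cfg$wander_amplitude *
      outer(rep(1, cfg$leads), sin(2 * pi * cfg$wander_freq * t +
                                     stats::runif(1, 0, 2 * pi)))
  if (cfg$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, cfg$noise_sd),
                        nrow(sig), ncol(sig))
  rec <- list(signal = sig, labels = labels, record_seed = record_seed)
  class(rec) <- "synthetic_record"
  rec
}

#' Generate a complete synthetic dataset
#'
#' Samples the annotation matrix, synthesizes all signals, and (optionally)
#' writes the dataset to disk: `signals.bin` (raw little-endian float32,
#' records x leads x samples, described by `meta.json`), `annotations.csv`
#' (dense binary), `hierarchy.json`, and the design's true correlation
#' matrices under `design_correlations/` for oracle checks.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory.
#' @param overwrite allow writing into an existing directory.
#' @return (Invisibly when writing) a dataset list: `signals` (n x leads x
#'   T array), `annotations`, `hierarchy`, `tree`, `cfg`.
#' @export
generate_dataset <- function(cfg, dir = NULL, overwrite = FALSE) {
  tree <- make_label_tree(cfg)
  ann <- sample_annotations(tree, cfg)
  nsamp <- round(cfg$sampling_rate * cfg$duration)
  signals <- array(NA_real_, c(cfg$n_records, cfg$leads, nsamp))
  labs <- tree$hierarchy$label
  for (r in seq_len(cfg$n_records)) {
    pos <- labs[ann$values[r, ] == 1]
    rs <- (cfg$seed * 100003 + r) %% .Machine$integer.max
    signals[r, , ] <- synthesize_signal(pos, tree, cfg, rs)$signal
  }
  ds <- list(signals = signals, annotations = ann,
             hierarchy = tree$hierarchy, tree = tree, cfg = cfg)
  if (!is.null(dir)) {
    if (dir.exists(dir) && !overwrite)
      stop("output directory exists; use overwrite = TRUE")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(dir, "signals.bin"), "wb")
    writeBin(as.vector(aperm(signals, c(3, 2, 1))), con,
             size = 4, endian = "little")
    close(con)
    jsonlite::write_json(
      list(n_records = cfg$n_records, leads = cfg$leads, samples = nsamp,
           sampling_rate = cfg$sampling_rate, layout = "sample-major",
           dtype = "float32", seed = cfg$seed),
      file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(record_id = seq_len(cfg$n_records),
                                ann$values, check.names = FALSE),
                     file.path(dir, "annotations.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(tree$hierarchy),
                         file.path(dir, "hierarchy.json"), dataframe = "columns")
    ddir <- file.path(dir, "design_correlations")
    dir.create(ddir, showWarnings = FALSE)
    utils::write.csv(tree$design_MS, file.path(ddir, "R_MS.csv"))
    utils::write.csv(tree$design_ME, file.path(ddir, "R_ME.csv"))
  }
  invisible(ds)
}
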