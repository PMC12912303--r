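#' Training configuration
#'
#' Reproduces the study regimen by default: SGD with momentum 0.9 and weight
#' decay 1e-5 for 130 epochs under a one-cycle-plus-sawtooth learning-rate
#' schedule — linear warmup 0.001 to 0.01 over the first 45 epochs, linear
#' decay back to 0.001 over the next 45, rapid (geometric) decay to the 1e-6
#' floor over 10 epochs, then three 10-epoch sawtooths each restarting at
#' 0.005 and decaying geometrically to the floor. Phase lengths must sum to
#' `epochs`; shorter training runs evaluate the same schedule at
#' proportionally scaled epochs.
#'
#' @param epochs total epochs.
#' @param batch_size minibatch size.
#' @param momentum,weight_decay SGD hyperparameters.
#' @param scheme `"shared"` (one trunk, one head per expert, loss = sum of
#'   the expert losses) or `"private"` (one full network per expert).
#' @param seed single seed driving initialization, shuffling and dropout.
#' @param val_fraction held-out fraction for model selection.
#' @param srr_weight coefficient on the ranking regularizer.
#' @param use_class_weights apply `w_i = N/N_i` in every BCE.
#' @param include_softmax_baseline also train an extra head with a full
#'   softmax activation (plain BCE), used as a consistency baseline; it is
#'   excluded from the aggregate.
#' @param select_best retain the epoch with the best validation macro AUPRC
#'   of the aggregate.
#' @param lr_start,lr_peak,lr_floor,sawtooth_restart schedule anchors.
#' @param warmup_epochs,down_epochs,fast_epochs,n_sawtooth,sawtooth_len
#'   schedule phase lengths.
#' @param verbose print one line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 130, batch_size = 64, momentum = 0.9,
                         weight_decay = 1e-5,
                         scheme = c("shared", "private"), seed = 1,
                         val_fraction = 0.2, srr_weight = 1,
                         use_class_weights = TRUE,
                         include_softmax_baseline = FALSE,
                         select_best = TRUE,
                         lr_start = 0.001, lr_peak = 0.01, lr_floor = 1e-6,
                         sawtooth_restart = 0.005,
                         warmup_epochs = 45, down_epochs = 45,
                         fast_epochs = 10, n_sawtooth = 3, sawtooth_len = 10,
                         verbose = FALSE) {
  scheme <- match.arg(scheme)
  cfg <- as.list(environment())
  class(cfg) <- "train_config"
  cfg
}

.plan_length <- function(cfg) {
  cfg$warmup_epochs + cfg$down_epochs + cfg$fast_epochs +
    cfg$n_sawtooth * cfg$sawtooth_len
}

#' Learning rate at a given epoch
#'
#' Evaluates the piecewise schedule of [train_config()]. With the default
#' configuration: 0.001 at epoch 0, peak 0.01 at epoch 44, back to 0.001 at
#' epoch 89, geometric decay to 1e-6 by epoch 99, and three sawtooths over
#' epochs 100-129 each restarting at 0.005 and decaying to 1e-6.
#'
#' @param epoch 0-based epoch, `0 <= epoch < epochs`.
#' @param cfg a [train_config()] whose phase lengths sum to its `epochs`.
#' @return Learning rate.
#' @export
lr_at <- function(epoch, cfg = train_config()) {
  plan <- .plan_length(cfg)
  if (plan != cfg$epochs)
    stop("schedule phase lengths (", plan, ") must sum to epochs (",
         cfg$epochs, ")")
  if (any(epoch < 0 | epoch >= cfg$epochs)) stop("epoch out of range")
  vapply(epoch, .lr_one, numeric(1), cfg = cfg)
}

.lr_one <- function(e, cfg) {
  w <- cfg$warmup_epochs; d <- cfg$down_epochs; f <- cfg$fast_epochs
  if (e < w)
    return(cfg$lr_start + (cfg$lr_peak - cfg$lr_start) * e / (w - 1))
  if (e < w + d)
    return(cfg$lr_peak + (cfg$lr_start - cfg$lr_peak) * (e - w + 1) / d)
  if (e < w + d + f) {
    frac <- (e - (w + d) + 1) / f
    return(cfg$lr_start * (cfg$lr_floor / cfg$lr_start)^frac)
  }
  phase <- (e - (w + d + f)) %% cfg$sawtooth_len
  cfg$sawtooth_restart *
    (cfg$lr_floor / cfg$sawtooth_restart)^(phase / (cfg$sawtooth_len - 1))
}

# schedule for runs shorter/longer than the canonical plan: evaluate the
# plan at the proportionally scaled epoch
.lr_scaled <- function(e, cfg) {
  plan <- .plan_length(cfg)
  cfg2 <- cfg; cfg2$epochs <- plan
  pe <- min(plan - 1, floor(e * plan / cfg$epochs))
  .lr_one(pe, cfg2)
}

#' Average expert predictions
#'
#' Element-wise arithmetic mean over experts. Accepts a list of equally
#' shaped activation matrices or an (records, labels, experts) array.
#'
#' @param preds per-expert activations in `[0, 1]`.
#' @return Matrix (records x labels).
#' @export
aggregate_predictions <- function(preds) {
  if (is.list(preds)) {
    d <- dim(preds[[1]])
    if (!all(vapply(preds, function(p) identical(dim(p), d), logical(1))))
      stop("expert prediction shapes differ")
    preds <- array(unlist(preds), c(d, length(preds)))
  }
  if (length(dim(preds)) != 3) stop("need records x labels x experts")
  if (min(preds) < 0 || max(preds) > 1)
    stop("activations must lie in [0, 1]")
  apply(preds, c(1, 2), mean)
}

.sgd_init <- function(par) lapply(par, function(p) p * 0)

.sgd_step <- function(par, opt, grads, lr, cfg) {
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + cfg$weight_decay * par[[nm]]
    opt[[nm]] <- cfg$momentum * opt[[nm]] + g
    par[[nm]] <- par[[nm]] - lr * opt[[nm]]
  }
  list(par = par, opt = opt)
}

# eval-mode per-expert activations for a signal array: (n, C, E)
.predict_sigma <- function(net, signals, specs, priors, cs,
                           batch_size = 256) {
  n <- dim(signals)[1]
  C <- net$spec$num_labels
  E <- length(specs)
  out <- array(NA_real_, c(n, C, E),
               dimnames = list(NULL, names(priors$N_i), names(specs)))
  starts <- seq(1, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, n)
    x <- aperm(signals[idx, , , drop = FALSE], c(2, 3, 1))
    tr <- .trunk_fw(net, x, training = FALSE)
    if (net$spec$scheme == "single") {
      f <- .gap_fw(tr$y)
      z <- .linear_fw(tr$net, "fc", f)
      for (e in seq_len(E))
        out[idx, , e] <- t(.act_forward(z, specs[[e]], priors, cs)$sig)
    } else {
      for (e in seq_len(E)) {
        hd <- .head_fw(tr$net, e, tr$y, training = FALSE)
        out[idx, , e] <- t(.act_forward(hd$z, specs[[e]], priors, cs)$sig)
      }
    }
  }
  out
}

#' Train the multi-expert ensemble
#'
#' Splits the dataset into training and validation parts, builds the
#' correlation set and class priors from the training split only (unless
#' supplied), and trains under the configured scheme: `shared` trains one
#' network with a shared trunk and one head per expert on the sum of the 12
#' expert losses; `private` trains 12 single-head networks, one per expert
#' loss. Each epoch logs every expert's mean training loss, the learning
#' rate and its validation macro AUPRC; the parameters from the epoch with
#' the best validation macro AUPRC of the aggregated prediction are
#' retained.
#'
#' @param dataset list with `signals` (array n x leads x time) and
#'   `annotations` (an [annotation_matrix()] or binary matrix).
#' @param cfg a [train_config()].
#' @param net_spec a [network_spec()]; its scheme is forced to match `cfg`
#'   (`multi` for shared, `single` for private). Defaults to a spec sized
#'   from the data.
#' @param cs,priors optional precomputed correlation set / priors; computed
#'   from the training split when `NULL`.
#' @param specs expert specifications, default [expert_grid()].
#' @return An `expert_ensemble` with the trained parameters, per-epoch log
#'   (`log`: epoch, expert, loss, lr, val_auprc), split indices and the
#'   objects needed for prediction.
#' @export
train_experts <- function(dataset, cfg = train_config(), net_spec = NULL,
                          cs = NULL, priors = NULL, specs = NULL) {
  signals <- dataset$signals
  ann <- dataset$annotations
  if (!inherits(ann, "annotation_matrix")) ann <- annotation_matrix(ann)
  n <- dim(signals)[1]
  if (n != ann$N) stop("signals and annotations disagree on record count")
  if (n < 2) stop("empty or degenerate dataset")
  set.seed(cfg$seed)
  if (is.null(specs)) specs <- expert_grid(srr_weight = cfg$srr_weight)
  n_grid <- length(specs)
  if (cfg$include_softmax_baseline) {
    specs <- c(specs, list(softmax_baseline = expert_spec("softmax", "longtailed")))
  }
  E <- length(specs)

  val_n <- max(1, round(cfg$val_fraction * n))
  perm <- sample(n)
  val_idx <- sort(perm[seq_len(val_n)])
  train_idx <- sort(perm[-seq_len(val_n)])
  if (length(train_idx) == 0) stop("empty training split")

  ann_train <- annotation_matrix(ann$values[train_idx, , drop = FALSE])
  if (is.null(cs)) cs <- build_correlation_set(ann_train)
  if (is.null(priors)) priors <- compute_priors(ann_train)

  if (is.null(net_spec)) {
    net_spec <- network_spec(
      scheme = if (cfg$scheme == "shared") "multi" else "single",
      input_length = dim(signals)[3], num_labels = ncol(ann$values),
      num_leads = dim(signals)[2], stem_channels = 8, channel_growth = 8,
      num_blocks = 4, shared_blocks = 3, num_experts = E)
  } else {
    net_spec$num_labels <- ncol(ann$values)
    if (cfg$scheme == "shared") {
      net_spec$scheme <- "multi"; net_spec$num_experts <- E
    } else net_spec$scheme <- "single"
  }

  Yall <- t(ann$values)                      # C x n
  if (cfg$scheme == "shared") {
    fit <- .train_shared(signals, Yall, train_idx, val_idx, cs, priors,
                         specs, n_grid, net_spec, cfg)
  } else {
    fit <- .train_private(signals, Yall, train_idx, val_idx, cs, priors,
                          specs, n_grid, net_spec, cfg)
  }

  model <- c(fit, list(scheme = cfg$scheme, specs = specs, n_grid = n_grid,
                       cs = cs, priors = priors, cfg = cfg,
                       net_spec = net_spec, labels = colnames(ann$values),
                       train_idx = train_idx, val_idx = val_idx))
  class(model) <- "expert_ensemble"
  model
}

.epoch_val <- function(nets_or_net, scheme, signals, val_idx, Yall, specs,
                       n_grid, priors, cs) {
  vs <- signals[val_idx, , , drop = FALSE]
  if (scheme == "shared") {
    sig <- .predict_sigma(nets_or_net, vs, specs, priors, cs)
  } else {
    C <- nrow(Yall)
    sig <- array(NA_real_, c(length(val_idx), C, length(specs)))
    for (e in seq_along(specs))
      sig[, , e] <- .predict_sigma(nets_or_net[[e]], vs, specs[e],
                                   priors, cs)[, , 1]
  }
  Yval <- t(Yall[, val_idx, drop = FALSE])
  per <- vapply(seq_along(specs), function(e)
    as.numeric(macro_auprc(sig[, , e], Yval)), numeric(1))
  agg <- aggregate_predictions(sig[, , seq_len(n_grid), drop = FALSE])
  list(per_expert = per, aggregate = as.numeric(macro_auprc(agg, Yval)))
}

.train_shared <- function(signals, Yall, train_idx, val_idx, cs, priors,
                          specs, n_grid, net_spec, cfg) {
  net <- build_network(net_spec)
  opt <- .sgd_init(net$par)
  log <- list()
  best <- list(score = -Inf, par = net$par, state = net$state, epoch = NA)
  for (ep in seq_len(cfg$epochs) - 1L) {
    lr <- .lr_scaled(ep, cfg)
    ord <- sample(train_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    eloss <- numeric(length(specs))
    for (bi in batches) {
      x <- aperm(signals[bi, , , drop = FALSE], c(2, 3, 1))
      Y <- Yall[, bi, drop = FALSE]
      tr <- .trunk_fw(net, x, training = TRUE)
      net <- tr$net
      acc <- new.env(parent = emptyenv())
      gfeat <- 0
      for (e in seq_along(specs)) {
        hd <- .head_fw(net, e, tr$y, training = TRUE)
        net <- hd$net
        lb <- .expert_loss_batch(Y, hd$z, specs[[e]], priors, cs,
                                 cfg$use_class_weights)
        if (!is.finite(lb$loss))
          stop("non-finite loss in expert ", names(specs)[e],
               " at epoch ", ep)
        eloss[e] <- eloss[e] + lb$loss * length(bi)
        gfeat <- gfeat + .head_bw(net, acc, e, hd, lb$grad)
      }
      .trunk_bw(net, acc, tr$caches, gfeat)
      stepped <- .sgd_step(net$par, opt, as.list(acc), lr, cfg)
      net$par <- stepped$par; opt <- stepped$opt
    }
    eloss <- eloss / length(train_idx)
    val <- .epoch_val(net, "shared", signals, val_idx, Yall, specs,
                      n_grid, priors, cs)
    log[[length(log) + 1]] <- data.frame(
      epoch = ep, expert = names(specs), loss = eloss, lr = lr,
      val_auprc = val$per_expert, agg_val_auprc = val$aggregate)
    if (cfg$verbose)
      message(sprintf("epoch %d  lr %.5f  loss %.4f  agg val AUPRC %.4f",
                      ep, lr, sum(eloss), val$aggregate))
    if (!cfg$select_best || val$aggregate > best$score)
      best <- list(score = val$aggregate, par = net$par,
                   state = net$state, epoch = ep)
  }
  net$par <- best$par; net$state <- best$state
  list(net = net, log = do.call(rbind, log), best_epoch = best$epoch,
       best_val_auprc = best$score)
}

.train_private <- function(signals, Yall, train_idx, val_idx, cs, priors,
                           specs, n_grid, net_spec, cfg) {
  nets <- vector("list", length(specs))
  log <- list()
  for (e in seq_along(specs)) {
    net <- build_network(net_spec)
    opt <- .sgd_init(net$par)
    best <- list(score = -Inf, par = net$par, state = net$state, epoch = NA)
    for (ep in seq_len(cfg$epochs) - 1L) {
      lr <- .lr_scaled(ep, cfg)
      ord <- sample(train_idx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tot <- 0
      for (bi in batches) {
        x <- aperm(signals[bi, , , drop = FALSE], c(2, 3, 1))
        Y <- Yall[, bi, drop = FALSE]
        tr <- .trunk_fw(net, x, training = TRUE)
        net <- tr$net
        f <- .gap_fw(tr$y)
        z <- .linear_fw(net, "fc", f)
        lb <- .expert_loss_batch(Y, z, specs[[e]], priors, cs,
                                 cfg$use_class_weights)
        if (!is.finite(lb$loss))
          stop("non-finite loss in expert ", names(specs)[e],
               " at epoch ", ep)
        tot <- tot + lb$loss * length(bi)
        acc <- new.env(parent = emptyenv())
        gF <- .linear_bw(net, acc, "fc", f, lb$grad)
        .trunk_bw(net, acc, tr$caches, .gap_bw(gF, dim(tr$y)))
        stepped <- .sgd_step(net$par, opt, as.list(acc), lr, cfg)
        net$par <- stepped$par; opt <- stepped$opt
      }
      val <- .epoch_val(list(net), "private", signals, val_idx, Yall,
                        specs[e], 1L, priors, cs)
      log[[length(log) + 1]] <- data.frame(
        epoch = ep, expert = names(specs)[e], loss = tot / length(train_idx),
        lr = lr, val_auprc = val$per_expert,
        agg_val_auprc = val$per_expert)
      if (!cfg$select_best || val$per_expert > best$score)
        best <- list(score = val$per_expert, par = net$par,
                     state = net$state, epoch = ep)
    }
    net$par <- best$par; net$state <- best$state
    nets[[e]] <- net
  }
  list(nets = nets, log = do.call(rbind, log), best_epoch = NA_integer_,
       best_val_auprc = NA_real_)
}

#' Per-expert and aggregated predictions of a trained ensemble
#'
#' @param model an `expert_ensemble` from [train_experts()].
#' @param signals array (n, leads, time).
#' @return List with `per_expert` (n x labels x experts activation array,
#'   experts in grid order plus any baseline head) and `aggregate` (n x
#'   labels mean over the 12 grid experts).
#' @export
predict_experts <- function(model, signals) {
  if (model$scheme == "shared") {
    sig <- .predict_sigma(model$net, signals, model$specs, model$priors,
                          model$cs)
  } else {
    n <- dim(signals)[1]
    C <- length(model$labels)
    sig <- array(NA_real_, c(n, C, length(model$specs)),
                 dimnames = list(NULL, model$labels, names(model$specs)))
    for (e in seq_along(model$specs))
      sig[, , e] <- .predict_sigma(model$nets[[e]], signals, model$specs[e],
                                   model$priors, model$cs)[, , 1]
  }
  list(per_expert = sig,
       aggregate = aggregate_predictions(
         sig[, , seq_len(model$n_grid), drop = FALSE]))
}

#' @export
print.expert_ensemble <- function(x, ...) {
  cat("expert_ensemble (", x$scheme, " scheme): ", length(x$specs),
      " experts, ", length(x$labels), " labels; best epoch ",
      x$best_epoch, " (val macro AUPRC ",
      round(x$best_val_auprc, 4), ")\n", sep = "")
  invisible(x)
}
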