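#' Specification of the multi-scale 1-D residual network
#'
#' The backbone is a stem multi-scale convolution (`num_leads` to
#' `stem_channels`), followed by `num_blocks` residual blocks whose output
#' channels follow `stem_channels + channel_growth * k` for block index
#' `k = 0, ..., num_blocks - 1`; each block halves the time axis. Every
#' multi-scale convolution runs four parallel kernels (lengths 3/5/9/17 by
#' default) with the output channels split evenly across branches, carries
#' no bias (batch normalization follows immediately), and blocks use
#' parameter-free shortcuts (stride-2 subsampling with zero-padded
#' channels). Global average pooling and a linear layer produce one logit
#' per label. The `multi` scheme shares the stem and the first
#' `shared_blocks` blocks and replicates the remaining `head_blocks` blocks
#' plus the linear layer once per expert.
#'
#' The full-scale configuration (7500-sample input, 254 labels, 8 blocks,
#' stem 64, growth 16) has 2.07 M trainable parameters in the single scheme.
#'
#' @param scheme `"single"` (one output head) or `"multi"` (one head per
#'   expert).
#' @param input_length number of time samples per lead.
#' @param num_labels number of output classes.
#' @param num_leads input channels (12-lead ECG).
#' @param stem_channels stem output channels; also block 0's output.
#' @param channel_growth channel increment per block.
#' @param num_blocks total residual blocks.
#' @param shared_blocks blocks in the shared trunk (`multi` scheme).
#' @param num_experts heads in the `multi` scheme.
#' @param dropout dropout rate inside each block.
#' @param kernel_lengths the four branch kernel lengths (odd).
#' @return A `network_spec` list.
#' @export
network_spec <- function(scheme = c("single", "multi"),
                         input_length = 7500, num_labels = 254,
                         num_leads = 12, stem_channels = 64,
                         channel_growth = 16, num_blocks = 8,
                         shared_blocks = 6, num_experts = 12,
                         dropout = 0.2, kernel_lengths = c(3, 5, 9, 17)) {
  scheme <- match.arg(scheme)
  if (any(kernel_lengths %% 2 != 1)) stop("kernel lengths must be odd")
  if (stem_channels %% 4 != 0 ||
      any((stem_channels + channel_growth * seq_len(num_blocks)) %% 4 != 0))
    stop("channel counts must be divisible by 4 (even split across branches)")
  min_len <- 2^num_blocks
  if (input_length < min_len)
    stop("input_length ", input_length, " too short to survive ", num_blocks,
         " stride-2 halvings; minimum is ", min_len)
  if (scheme == "multi" && shared_blocks >= num_blocks)
    stop("multi scheme needs at least one head block")
  channels <- stem_channels + channel_growth * (0:(num_blocks - 1))
  spec <- list(scheme = scheme, input_length = input_length,
               num_labels = num_labels, num_leads = num_leads,
               stem_channels = stem_channels, channel_growth = channel_growth,
               num_blocks = num_blocks, shared_blocks = shared_blocks,
               head_blocks = num_blocks - shared_blocks,
               num_experts = num_experts, dropout = dropout,
               kernel_lengths = as.integer(kernel_lengths),
               channels = channels)
  class(spec) <- "network_spec"
  spec
}

# ---- parameter initialisation (Kaiming) ----

.init_msconv <- function(par, prefix, cin, cout, kernels) {
  cb <- cout / 4
  for (i in seq_along(kernels)) {
    K <- kernels[i]
    sd <- sqrt(2 / (cin * K))
    par[[paste0(prefix, ".W", i)]] <-
      matrix(stats::rnorm(cb * cin * K, 0, sd), cb, cin * K)
  }
  par
}

.init_module <- function(par, state, prefix, cin, cout, kernels) {
  par <- .init_msconv(par, prefix, cin, cout, kernels)
  par[[paste0(prefix, ".g")]] <- rep(1, cout)
  par[[paste0(prefix, ".b")]] <- rep(0, cout)
  state[[paste0(prefix, ".rm")]] <- rep(0, cout)
  state[[paste0(prefix, ".rv")]] <- rep(1, cout)
  list(par = par, state = state)
}

.init_block <- function(par, state, prefix, cin, cout, kernels) {
  ps <- .init_module(par, state, paste0(prefix, ".m1"), cin, cout, kernels)
  .init_module(ps$par, ps$state, paste0(prefix, ".m2"), cout, cout, kernels)
}

.init_linear <- function(par, prefix, cin, nout) {
  par[[paste0(prefix, ".W")]] <-
    matrix(stats::rnorm(nout * cin, 0, sqrt(2 / cin)), nout, cin)
  par[[paste0(prefix, ".b")]] <- rep(0, nout)
  par
}

#' Build a network from a specification
#'
#' Allocates and Kaiming-initializes all trainable parameters. Two builds
#' with the same spec and seed are identical.
#'
#' @param spec a [network_spec()].
#' @param seed optional integer seed for the initialization.
#' @return An `msdnn` object holding the parameter list (`par`),
#'   batch-normalization running statistics (`state`) and the spec.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  if (!is.null(seed)) set.seed(seed)
  par <- list(); state <- list()
  kr <- spec$kernel_lengths
  ps <- .init_module(par, state, "stem", spec$num_leads, spec$stem_channels, kr)
  par <- ps$par; state <- ps$state
  cin <- spec$stem_channels
  shared_upto <- if (spec$scheme == "multi") spec$shared_blocks else spec$num_blocks
  for (k in seq_len(shared_upto)) {
    cout <- spec$channels[k]
    ps <- .init_block(par, state, paste0("blk", k - 1), cin, cout, kr)
    par <- ps$par; state <- ps$state
    cin <- cout
  }
  if (spec$scheme == "single") {
    par <- .init_linear(par, "fc", cin, spec$num_labels)
  } else {
    trunk_c <- cin
    for (e in seq_len(spec$num_experts)) {
      cin <- trunk_c
      for (k in (spec$shared_blocks + 1):spec$num_blocks) {
        cout <- spec$channels[k]
        ps <- .init_block(par, state,
                          sprintf("h%d.blk%d", e, k - 1), cin, cout, kr)
        par <- ps$par; state <- ps$state
        cin <- cout
      }
      par <- .init_linear(par, sprintf("h%d.fc", e), cin, spec$num_labels)
    }
  }
  net <- list(spec = spec, par = par, state = state)
  class(net) <- "msdnn"
  net
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar: convolution weights, batch-normalization
#' scale and shift, linear weights and biases. Running statistics are not
#' parameters.
#'
#' @param net an `msdnn` from [build_network()].
#' @return Integer count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$par, length, integer(1)))
}

#' Number of weight layers
#'
#' Convolutional and linear layers on one input-to-output path (batch
#' normalizations not counted): stem + two convolutions per block + the
#' final linear layer. The reference single-expert configuration has 18.
#'
#' @param spec a [network_spec()].
#' @return Integer.
#' @export
layer_count <- function(spec) {
  1L + 2L * spec$num_blocks + 1L
}

#' @export
print.msdnn <- function(x, ...) {
  cat("msdnn (", x$spec$scheme, "): ", x$spec$num_blocks, " blocks, ",
      count_parameters(x), " parameters (",
      round(count_parameters(x) / 1e6, 2), " M)\n", sep = "")
  invisible(x)
}

# ---- forward / backward ----
# Activations are cubes (channels, time, batch). `acc` is an environment
# collecting parameter gradients by name during backward.

.bn_fw <- function(net, prefix, x, training) {
  g <- net$par[[paste0(prefix, ".g")]]
  b <- net$par[[paste0(prefix, ".b")]]
  eps <- 1e-5
  if (training) {
    mu <- rowMeans(x, dims = 1)
    xc <- x - mu
    v <- rowMeans(xc * xc, dims = 1)
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * invstd
    mom <- 0.1
    net$state[[paste0(prefix, ".rm")]] <-
      (1 - mom) * net$state[[paste0(prefix, ".rm")]] + mom * mu
    net$state[[paste0(prefix, ".rv")]] <-
      (1 - mom) * net$state[[paste0(prefix, ".rv")]] + mom * v
    y <- g * xhat + b
    list(net = net, y = y, cache = list(xhat = xhat, invstd = invstd, g = g))
  } else {
    rm <- net$state[[paste0(prefix, ".rm")]]
    rv <- net$state[[paste0(prefix, ".rv")]]
    y <- g * ((x - rm) / sqrt(rv + eps)) + b
    list(net = net, y = y, cache = NULL)
  }
}

.bn_bw <- function(acc, prefix, cache, gy) {
  M <- prod(dim(gy)[2:3])
  dbeta <- rowSums(gy, dims = 1)
  dgamma <- rowSums(gy * cache$xhat, dims = 1)
  acc[[paste0(prefix, ".g")]] <- dgamma
  acc[[paste0(prefix, ".b")]] <- dbeta
  cache$g * cache$invstd * (gy - dbeta / M - cache$xhat * dgamma / M)
}

.module_fw <- function(net, prefix, x, stride, training) {
  W <- lapply(seq_len(4), function(i) net$par[[paste0(prefix, ".W", i)]])
  conv <- msconv_forward(x, W, net$spec$kernel_lengths, stride)
  bn <- .bn_fw(net, prefix, conv, training)
  y <- pmax(bn$y, 0)
  list(net = bn$net, y = y,
       cache = list(x = x, conv = conv, bn = bn$cache,
                    mask = bn$y > 0, stride = stride))
}

.module_bw <- function(net, acc, prefix, cache, gy) {
  gy <- gy * cache$mask
  gconv <- .bn_bw(acc, prefix, cache$bn, gy)
  W <- lapply(seq_len(4), function(i) net$par[[paste0(prefix, ".W", i)]])
  bw <- msconv_backward(cache$x, W, net$spec$kernel_lengths,
                        cache$stride, gconv)
  for (i in seq_len(4)) acc[[paste0(prefix, ".W", i)]] <- bw$gW[[i]]
  bw$gx
}

# parameter-free shortcut: stride-2 subsample, zero-pad channels
.shortcut_fw <- function(x, cout) {
  d <- dim(x)
  idx <- seq(1, d[2], by = 2)
  y <- array(0, c(cout, length(idx), d[3]))
  y[seq_len(d[1]), , ] <- x[, idx, , drop = FALSE]
  y
}

.shortcut_bw <- function(gy, dimx) {
  gx <- array(0, dimx)
  idx <- seq(1, dimx[2], by = 2)
  gx[, idx, ] <- gy[seq_len(dimx[1]), , , drop = FALSE]
  gx
}

.block_fw <- function(net, prefix, x, training) {
  m1 <- .module_fw(net, paste0(prefix, ".m1"), x, 2L, training)
  m2 <- .module_fw(m1$net, paste0(prefix, ".m2"), m1$y, 1L, training)
  net <- m2$net
  rate <- net$spec$dropout
  if (training && rate > 0) {
    keep <- 1 - rate
    dmask <- array((stats::runif(length(m2$y)) < keep) / keep, dim(m2$y))
    y2 <- m2$y * dmask
  } else {
    dmask <- NULL
    y2 <- m2$y
  }
  cout <- dim(y2)[1]
  y <- y2 + .shortcut_fw(x, cout)
  list(net = net, y = y,
       cache = list(m1 = m1$cache, m2 = m2$cache, dmask = dmask,
                    dimx = dim(x)))
}

.block_bw <- function(net, acc, prefix, cache, gy) {
  gmain <- if (is.null(cache$dmask)) gy else gy * cache$dmask
  g1 <- .module_bw(net, acc, paste0(prefix, ".m2"), cache$m2, gmain)
  gx <- .module_bw(net, acc, paste0(prefix, ".m1"), cache$m1, g1)
  gx + .shortcut_bw(gy, cache$dimx)
}

.gap_fw <- function(x) apply(x, 3, rowMeans)   # (C, T, B) -> (C, B)

.gap_bw <- function(gF, dimx) {
  # broadcast gF (C, B) across the time axis, scaled by 1/T
  aperm(array(gF / dimx[2], c(dimx[1], dimx[3], dimx[2])), c(1, 3, 2))
}

.linear_fw <- function(net, prefix, f) {
  W <- net$par[[paste0(prefix, ".W")]]
  b <- net$par[[paste0(prefix, ".b")]]
  W %*% f + b
}

.linear_bw <- function(net, acc, prefix, f, gz) {
  acc[[paste0(prefix, ".W")]] <- gz %*% t(f)
  acc[[paste0(prefix, ".b")]] <- rowSums(gz)
  t(net$par[[paste0(prefix, ".W")]]) %*% gz
}

# trunk = stem + shared blocks (all blocks in the single scheme)
.trunk_fw <- function(net, x, training) {
  caches <- list()
  st <- .module_fw(net, "stem", x, 1L, training)
  net <- st$net; caches$stem <- st$cache
  h <- st$y
  upto <- if (net$spec$scheme == "multi") net$spec$shared_blocks else net$spec$num_blocks
  for (k in seq_len(upto)) {
    bl <- .block_fw(net, paste0("blk", k - 1), h, training)
    net <- bl$net; caches[[paste0("blk", k - 1)]] <- bl$cache
    h <- bl$y
  }
  list(net = net, y = h, caches = caches)
}

.trunk_bw <- function(net, acc, caches, gy) {
  upto <- if (net$spec$scheme == "multi") net$spec$shared_blocks else net$spec$num_blocks
  g <- gy
  for (k in rev(seq_len(upto)))
    g <- .block_bw(net, acc, paste0("blk", k - 1), caches[[paste0("blk", k - 1)]], g)
  .module_bw(net, acc, "stem", caches$stem, g)
}

.head_fw <- function(net, e, h, training) {
  spec <- net$spec
  caches <- list()
  for (k in (spec$shared_blocks + 1):spec$num_blocks) {
    prefix <- sprintf("h%d.blk%d", e, k - 1)
    bl <- .block_fw(net, prefix, h, training)
    net <- bl$net; caches[[prefix]] <- bl$cache
    h <- bl$y
  }
  f <- .gap_fw(h)
  z <- .linear_fw(net, sprintf("h%d.fc", e), f)
  list(net = net, z = z, caches = caches, f = f, dimh = dim(h))
}

.head_bw <- function(net, acc, e, head_cache, gz) {
  spec <- net$spec
  gF <- .linear_bw(net, acc, sprintf("h%d.fc", e), head_cache$f, gz)
  g <- .gap_bw(gF, head_cache$dimh)
  for (k in rev((spec$shared_blocks + 1):spec$num_blocks)) {
    prefix <- sprintf("h%d.blk%d", e, k - 1)
    g <- .block_bw(net, acc, prefix, head_cache$caches[[prefix]], g)
  }
  g
}

#' Forward pass
#'
#' Maps a batch of ECG signals to logits. Input is an array of shape
#' (records, leads, time); output is (records, labels) for the single
#' scheme, or (records, experts, labels) for the multi scheme.
#'
#' @param net an `msdnn`.
#' @param signals array (n, leads, time) or a cube (leads, time, n).
#' @return Logit array.
#' @export
network_forward <- function(net, signals) {
  x <- .as_batch_cube(signals, net$spec)
  tr <- .trunk_fw(net, x, training = FALSE)
  if (net$spec$scheme == "single") {
    f <- .gap_fw(tr$y)
    z <- .linear_fw(tr$net, "fc", f)          # labels x B
    return(t(z))
  }
  B <- dim(x)[3]
  out <- array(NA_real_, c(B, net$spec$num_experts, net$spec$num_labels))
  for (e in seq_len(net$spec$num_experts)) {
    hd <- .head_fw(tr$net, e, tr$y, training = FALSE)
    out[, e, ] <- t(hd$z)
  }
  out
}

.as_batch_cube <- function(signals, spec) {
  d <- dim(signals)
  if (length(d) != 3) stop("signals must be a 3-d array")
  if (d[1] == spec$num_leads && d[2] == spec$input_length) return(signals)
  if (d[2] == spec$num_leads && d[3] == spec$input_length)
    return(aperm(signals, c(2, 3, 1)))
  stop("signal dimensions ", paste(d, collapse = "x"),
       " do not match the network spec (", spec$num_leads, " leads x ",
       spec$input_length, " samples)")
}

#' Save / load network weights
#'
#' Weights go to an RDS file with a JSON sidecar recording the spec.
#'
#' @param net an `msdnn`.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(net$spec[setdiff(names(net$spec), "channels")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) readRDS(path)
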