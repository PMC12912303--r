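.canonical_leads <- c("I", "II", "III", "AVR", "AVL", "AVF",
                      paste0("V", 1:6))

#' A single ECG record
#'
#' @param signal leads x samples numeric matrix, leads in canonical order
#'   (I, II, III, AVR, AVL, AVF, V1-V6).
#' @param sampling_rate Hz.
#' @param record_id identifier.
#' @return An `ecg_record` list.
#' @export
ecg_record <- function(signal, sampling_rate, record_id = "record") {
  signal <- as.matrix(signal)
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  rec <- list(signal = signal, sampling_rate = sampling_rate,
              record_id = record_id)
  class(rec) <- "ecg_record"
  rec
}

#' Zero-phase Butterworth high-pass filter
#'
#' The study's pretreatment: a 5th-order Butterworth high-pass with a
#' 0.5 Hz cutoff, removing baseline wander while preserving the
#' high-frequency diagnostic content. Applied forward-backward
#' (zero-phase) per lead so waveform morphology is not shifted; the
#' two-pass magnitude response is the squared single-pass Butterworth
#' response.
#'
#' @param rec an [ecg_record()], or a bare leads x samples matrix with
#'   `sampling_rate` supplied.
#' @param cutoff high-pass cutoff in Hz (must be below Nyquist).
#' @param order filter order.
#' @param sampling_rate needed when `rec` is a bare matrix.
#' @return Filtered object of the same type and shape.
#' @export
highpass_filter <- function(rec, cutoff = 0.5, order = 5,
                            sampling_rate = NULL) {
  if (inherits(rec, "ecg_record")) {
    fs <- rec$sampling_rate
    x <- rec$signal
  } else {
    if (is.null(sampling_rate)) stop("sampling_rate required for a bare matrix")
    fs <- sampling_rate
    x <- as.matrix(rec)
  }
  if (cutoff >= fs / 2)
    stop("cutoff ", cutoff, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  sos <- .butter_highpass_sos(order, cutoff / (fs / 2))
  pad <- ceiling(3 * fs / cutoff)
  y <- t(apply(x, 1, function(lead) .filtfilt_sos(sos, lead, pad)))
  if (inherits(rec, "ecg_record")) {
    rec$signal <- y
    rec
  } else y
}

# Butterworth high-pass design in second-order sections (bilinear transform
# with prewarping). Cascaded biquads keep the recursion well conditioned at
# very low normalized cutoffs, where a single expanded polynomial loses
# several digits. Wn is the cutoff as a fraction of Nyquist.
.butter_highpass_sos <- function(order, Wn) {
  wc <- tan(pi * Wn / 2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # analog LP poles
  p_hp <- wc / p_lp                                          # LP -> HP
  z_dig <- (1 + p_hp) / (1 - p_hp)                           # bilinear
  # overall gain: unity response at Nyquist (z = -1); zeros all at z = +1
  gain <- Re(prod(-1 - z_dig) / (-2)^order)
  sections <- list()
  poles <- z_dig[order(abs(Im(z_dig)), decreasing = TRUE)]
  i <- 1
  while (i <= order) {
    if (i + 1 <= order && abs(Im(poles[i])) > 1e-12) {
      p <- poles[i]                       # with its conjugate at i + 1
      sections[[length(sections) + 1]] <-
        list(b = c(1, -2, 1), a = c(1, -2 * Re(p), Mod(p)^2))
      i <- i + 2
    } else {
      sections[[length(sections) + 1]] <-
        list(b = c(1, -1, 0), a = c(1, -Re(poles[i]), 0))
      i <- i + 1
    }
  }
  sections[[1]]$b <- sections[[1]]$b * gain
  sections
}

.sos_pass <- function(sos, x) {
  for (s in sos) {
    zi <- .lfilter_zi(s$b, s$a)
    x <- lfilter_df2t(s$b, s$a, x, zi * x[1])
  }
  x
}

# zero-phase cascade: odd-reflection padding sized to the filter's settling
# time, then one forward and one time-reversed pass
.filtfilt_sos <- function(sos, x, pad) {
  n <- length(x)
  x <- x - mean(x)           # high-pass has zero DC gain; remove it exactly
  pad <- min(pad, n - 1)
  ext <- c(2 * x[1] - x[(pad + 1):2], x,
           2 * x[n] - x[(n - 1):(n - pad)])
  y <- .sos_pass(sos, ext)
  y <- rev(.sos_pass(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Filter every record of a signal array
#'
#' @param signals array (records, leads, samples).
#' @param sampling_rate Hz.
#' @inheritParams highpass_filter
#' @return Filtered array, same shape.
#' @export
highpass_dataset <- function(signals, sampling_rate, cutoff = 0.5,
                             order = 5) {
  for (r in seq_len(dim(signals)[1]))
    signals[r, , ] <- highpass_filter(signals[r, , ], cutoff, order,
                                      sampling_rate = sampling_rate)
  signals
}

# steady-state filter state for a unit step: makes the forward-backward
# passes transient-free at the edges
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  A <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  solve(diag(n - 1) - t(A), b[2:n] - a[2:n] * b[1])
}

# ---- minimal WFDB support (header + format 16/80 signal files) ----

#' Read a WFDB record
#'
#' Minimal reader for WFDB records (the PTB-XL layout): parses the `.hea`
#' header and the binary signal file for formats 16 (16-bit little-endian)
#' and 80 (8-bit offset binary), applies gain and baseline to get physical
#' units, and reorders the leads into the canonical order I, II, III, AVR,
#' AVL, AVF, V1-V6. Malformed headers, unknown lead names or missing leads
#' are rejected with descriptive errors rather than truncated.
#'
#' @param path record path without extension (e.g. `dir/rec001`).
#' @return An [ecg_record()].
#' @export
read_wfdb_record <- function(path) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 4) stop("malformed WFDB header line: ", lines[1])
  nsig <- as.integer(hdr[2]); fs <- as.numeric(hdr[3])
  nsamp <- as.integer(hdr[4])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp))
    stop("malformed WFDB header fields in ", hea)
  if (length(lines) < 1 + nsig) stop("header declares ", nsig,
                                     " signals but lists fewer")
  sig <- matrix(NA_real_, nsig, nsamp)
  leads <- character(nsig)
  fname <- NULL; fmt <- NULL; gain <- numeric(nsig); base <- numeric(nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(f) < 9) stop("malformed signal line in ", hea, ": ", lines[1 + i])
    if (is.null(fname)) fname <- f[1]
    else if (!identical(fname, f[1]))
      stop("multi-file WFDB records are not supported")
    fmt <- as.integer(sub("x.*$", "", f[2]))
    g <- strsplit(f[3], "[(/]")[[1]][1]
    gain[i] <- as.numeric(g)
    b <- regmatches(f[3], regexpr("\\(([-0-9]+)\\)", f[3]))
    base[i] <- if (length(b)) as.numeric(gsub("[()]", "", b)) else 0
    leads[i] <- toupper(f[9])
  }
  if (!fmt %in% c(16L, 80L))
    stop("unsupported WFDB signal format ", fmt, " (only 16 and 80)")
  datpath <- file.path(dirname(path), fname)
  if (!file.exists(datpath)) stop("signal file not found: ", datpath)
  con <- file(datpath, "rb")
  on.exit(close(con))
  if (fmt == 16L) {
    raw <- readBin(con, "integer", n = nsig * nsamp, size = 2,
                   endian = "little", signed = TRUE)
  } else {
    raw <- readBin(con, "integer", n = nsig * nsamp, size = 1,
                   signed = FALSE) - 128L
  }
  if (length(raw) < nsig * nsamp)
    stop("signal file shorter than header declares: ", datpath)
  adc <- matrix(raw, nrow = nsig)      # interleaved sample frames
  phys <- (adc - base) / ifelse(gain == 0, 200, gain)
  unknown <- setdiff(leads, .canonical_leads)
  if (length(unknown))
    stop("unknown lead name(s): ", paste(unknown, collapse = ", "))
  if (nsig == 12 && length(setdiff(.canonical_leads, leads)))
    stop("missing lead(s): ",
         paste(setdiff(.canonical_leads, leads), collapse = ", "))
  ord <- match(intersect(.canonical_leads, leads), leads)
  phys <- phys[ord, , drop = FALSE]
  rownames(phys) <- leads[ord]
  ecg_record(phys, fs, basename(path))
}

#' Write a WFDB record (format 16)
#'
#' Companion writer used for round-trip testing and export: quantizes the
#' physical signal with the given gain and writes a `.hea`/`.dat` pair.
#'
#' @param rec an [ecg_record()].
#' @param path record path without extension.
#' @param gain ADC units per physical unit.
#' @param leads lead names, defaulting to the canonical 12.
#' @return `path`, invisibly.
#' @export
write_wfdb_record <- function(rec, path, gain = 1000,
                              leads = NULL) {
  nsig <- nrow(rec$signal); nsamp <- ncol(rec$signal)
  if (is.null(leads))
    leads <- if (!is.null(rownames(rec$signal))) rownames(rec$signal)
             else .canonical_leads[seq_len(nsig)]
  adc <- round(rec$signal * gain)
  if (any(abs(adc) > 32767)) stop("signal overflows 16-bit range at gain ", gain)
  base <- basename(path)
  hea <- c(paste(base, nsig, rec$sampling_rate, nsamp),
           vapply(seq_len(nsig), function(i)
             paste(paste0(base, ".dat"), 16, paste0(gain, "(0)/mV"),
                   16, 0, 0, 0, 0, leads[i]), character(1)))
  writeLines(hea, paste0(path, ".hea"))
  con <- file(file.path(dirname(path), paste0(base, ".dat")), "wb")
  writeBin(as.integer(adc), con, size = 2, endian = "little")
  close(con)
  invisible(path)
}

#' Read a dataset directory written by [generate_dataset()]
#'
#' @param dir dataset directory containing `signals.bin`, `meta.json`,
#'   `annotations.csv`, `hierarchy.json`.
#' @return A dataset list: `signals`, `annotations`, `hierarchy`,
#'   `sampling_rate`.
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  n <- meta$n_records; L <- meta$leads; S <- meta$samples
  con <- file(file.path(dir, "signals.bin"), "rb")
  raw <- readBin(con, "numeric", n = n * L * S, size = 4, endian = "little")
  close(con)
  if (length(raw) != n * L * S)
    stop("signals.bin holds ", length(raw), " values; meta.json declares ",
         n * L * S)
  signals <- aperm(array(raw, c(S, L, n)), c(3, 2, 1))
  df <- utils::read.csv(file.path(dir, "annotations.csv"),
                        check.names = FALSE)
  ann <- annotation_matrix(as.matrix(df[, -1, drop = FALSE]))
  hierarchy <- read_hierarchy(file.path(dir, "hierarchy.json"))
  list(signals = signals, annotations = ann, hierarchy = hierarchy,
       sampling_rate = meta$sampling_rate)
}

#' Write predictions to disk
#'
#' Long-format CSV (`record_id`, `label`, `score`, `decision`) plus a JSON
#' summary with the thresholds and per-label positive-prediction counts.
#'
#' @param path output stem; writes `<path>.csv` and `<path>.json`.
#' @param aggregate records x labels activation matrix.
#' @param thresholds per-label decision thresholds.
#' @param record_ids optional identifiers.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(path, aggregate, thresholds,
                              record_ids = NULL) {
  n <- nrow(aggregate); C <- ncol(aggregate)
  labs <- colnames(aggregate) %||% as.character(seq_len(C))
  if (is.null(record_ids)) record_ids <- seq_len(n)
  thr <- rep(thresholds, length.out = C)
  df <- data.frame(
    record_id = rep(record_ids, times = C),
    label = rep(labs, each = n),
    score = as.vector(aggregate),
    decision = as.integer(as.vector(sweep(aggregate, 2, thr, ">="))))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_records = n, labels = labs, thresholds = thr,
         positive_counts = colSums(sweep(aggregate, 2, thr, ">="))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#' @param path output stem used when writing.
#' @return records x labels score matrix (attribute `decisions` carries the
#'   binary matrix).
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"))
  labs <- unique(df$label)
  ids <- unique(df$record_id)
  S <- matrix(df$score, length(ids), length(labs),
              dimnames = list(ids, labs))
  D <- matrix(df$decision, length(ids), length(labs),
              dimnames = list(ids, labs))
  attr(S, "decisions") <- D
  S
}

#' Read a YAML run configuration
#'
#' One file with sections `data`, `model`, `loss`, `train`, `eval`; absent
#' sections fall back to package defaults.
#'
#' @param path YAML file.
#' @return Named list of sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (s in c("data", "model", "loss", "train", "eval"))
    if (is.null(cfg[[s]])) cfg[[s]] <- list()
  cfg
}
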