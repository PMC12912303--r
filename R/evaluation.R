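#' Area under the ROC curve
#'
#' Normalized Mann-Whitney U statistic: the probability that a random
#' positive outranks a random negative, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary ground truth, same length.
#' @return AUROC in `[0, 1]`, or `NA` when either class is absent
#'   (undefined-metric signal; excluded from macro averages).
#' @export
auroc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise, non-interpolated estimator: records are ranked by descending
#' score (ties broken by stable original index) and the precisions at each
#' positive's rank are averaged.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`, or `NA` with no positives.
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1)
  if (np == 0) return(NA_real_)
  ord <- order(-scores)           # stable: ties keep original index order
  y <- labels[ord]
  hits <- cumsum(y)
  mean((hits / seq_along(y))[y == 1])
}

#' Macro (mean per-label) average precision
#'
#' Mean of per-label AUPRC over the columns of a score matrix; labels with
#' no positives are undefined and excluded from the mean (their count is
#' attached as attribute `n_undefined`).
#'
#' @param scores records x labels score matrix.
#' @param truth records x labels binary matrix.
#' @return Scalar macro AUPRC.
#' @export
macro_auprc <- function(scores, truth) {
  vals <- vapply(seq_len(ncol(truth)),
                 function(j) auprc(scores[, j], truth[, j]), numeric(1))
  out <- mean(vals, na.rm = TRUE)
  attr(out, "n_undefined") <- sum(is.na(vals))
  out
}

#' Break-even decision threshold
#'
#' The candidate threshold (over the sorted unique scores, applied as
#' "predict positive when score >= t") minimizing |precision - recall|,
#' ties resolved toward the lower threshold (higher sensitivity). The
#' returned value is the midpoint between the chosen score and the next
#' lower unique score, so that perfectly separated scores yield the middle
#' of the separating gap; if no lower score exists, a small offset below the
#' chosen score is returned (predicting everything positive).
#'
#' @inheritParams auroc
#' @return Threshold in `(0, 1)` scale of the scores, or `NA` with no
#'   positives.
#' @export
break_even_threshold <- function(scores, labels) {
  if (sum(labels == 1) == 0) return(NA_real_)
  cand <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels == 1)
  gap <- vapply(cand, function(t) {
    pred <- scores >= t
    prec <- sum(labels[pred]) / max(sum(pred), 1)
    rec <- sum(labels[pred]) / np
    abs(prec - rec)
  }, numeric(1))
  # ties toward the lowest threshold = highest sensitivity
  pick <- max(which(gap == min(gap)))
  t_star <- cand[pick]
  lower <- cand[cand < t_star]
  if (length(lower)) (t_star + max(lower)) / 2 else t_star - 1e-6
}

#' Label-wise and exam-wise confusion metrics
#'
#' Confusion counts and derived rates computed two ways: per label across
#' records (label-wise) and per record across labels, then averaged
#' (exam-wise). Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' F1 = 2TP/(2TP+FP+FN), accuracy = (TP+TN)/total.
#'
#' @param pred binary prediction matrix (records x labels).
#' @param truth binary truth matrix, same shape.
#' @return A `metric_report` list: `label` (per-label data.frame), `exam`
#'   (averaged per-record counts and derived rates), `macro` (means of the
#'   label-wise rates).
#' @export
confusion_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  derived <- function(tp, tn, fp, fn) {
    list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
         f1 = 2 * tp / (2 * tp + fp + fn),
         accuracy = (tp + tn) / (tp + tn + fp + fn))
  }
  cnt <- function(margin) {
    tp <- apply(pred * truth, margin, sum)
    fp <- apply(pred * (1 - truth), margin, sum)
    fn <- apply((1 - pred) * truth, margin, sum)
    tn <- apply((1 - pred) * (1 - truth), margin, sum)
    list(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  lw <- cnt(2)
  ld <- derived(lw$tp, lw$tn, lw$fp, lw$fn)
  label <- data.frame(label = colnames(truth) %||% seq_len(ncol(truth)),
                      TP = lw$tp, TN = lw$tn, FP = lw$fp, FN = lw$fn,
                      Sen = ld$sensitivity, Spe = ld$specificity,
                      F1 = ld$f1, Acc = ld$accuracy)
  ew <- lapply(cnt(1), mean)
  ed <- derived(ew$tp, ew$tn, ew$fp, ew$fn)
  out <- list(label = label,
              exam = c(list(TP = ew$tp, TN = ew$tn, FP = ew$fp, FN = ew$fn),
                       ed),
              macro = lapply(ld, mean, na.rm = TRUE))
  class(out) <- "metric_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction-consistency diagnostics
#'
#' Two failure modes of thresholded multi-label predictions against the
#' label correlations: predicting both members of a mutually exclusive pair
#' for the same record, and predicting a label without one of its symbiotic
#' ancestors (a broken hierarchy chain).
#'
#' @param sigma aggregated activation matrix (records x labels).
#' @param thr per-label thresholds (recycled if scalar).
#' @param cs correlation set over the same labels.
#' @return List: `exclusive_violation_rate` (fraction of records predicting
#'   at least one exclusive pair) and `broken_chain_rate` (fraction of
#'   records with a predicted label whose symbiotic ancestor is not
#'   predicted).
#' @export
consistency_report <- function(sigma, thr, cs) {
  P <- sweep(sigma, 2, rep(thr, length.out = ncol(sigma)), ">=") * 1
  excl <- rowSums((P %*% cs$R_ME) * P) > 0
  # R_MS[i, j] = 1: i is an ancestor of j; chain broken when j predicted
  # but some ancestor i is not
  missing_anc <- ((1 - P) %*% cs$R_MS) * P
  broken <- rowSums(missing_anc) > 0
  list(exclusive_violation_rate = mean(excl),
       broken_chain_rate = mean(broken))
}

#' Bland-Altman agreement between two per-label metric vectors
#'
#' @param a,b numeric vectors of equal length `>= 2` (e.g. per-label AUPRC
#'   of two models).
#' @return List: `mean_diff` (mean of a - b), `loa` (mean +/- 1.96 sd), and
#'   `max_abs_diff`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) stop("need equal length >= 2")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
       max_abs_diff = max(abs(d)))
}

#' Paired t-test on per-label metrics
#'
#' Two-sided paired t-test (e.g. per-label AUPRC of two models), the study's
#' significance protocol at alpha = 0.05.
#'
#' @param a,b paired numeric vectors, length `>= 2`.
#' @return List: `t`, `p`, `df`. Zero-variance differences give `NA` values
#'   with a warning (undefined signal).
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2) stop("need equal length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero-variance differences: t statistic undefined")
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Full evaluation report for a score matrix
#'
#' Per-label AUROC and AUPRC plus thresholded confusion metrics in one
#' table (the label-wise report layout), with exam-wise averages and macro
#' summaries. Thresholds default to per-label break-even points computed on
#' the scores themselves.
#'
#' @param scores records x labels activation matrix.
#' @param truth records x labels binary matrix.
#' @param thresholds per-label thresholds; `NULL` for break-even.
#' @return A `metric_report` with an added `label` table carrying AUROC /
#'   AUPRC columns and the `thresholds` used.
#' @export
metric_report <- function(scores, truth, thresholds = NULL) {
  C <- ncol(truth)
  if (is.null(thresholds))
    thresholds <- vapply(seq_len(C), function(j)
      break_even_threshold(scores[, j], truth[, j]), numeric(1))
  thresholds[is.na(thresholds)] <- 0.5
  pred <- sweep(scores, 2, thresholds, ">=") * 1
  rep <- confusion_metrics(pred, truth)
  rep$label$AUROC <- vapply(seq_len(C), function(j)
    auroc(scores[, j], truth[, j]), numeric(1))
  rep$label$AUPRC <- vapply(seq_len(C), function(j)
    auprc(scores[, j], truth[, j]), numeric(1))
  cols <- c("label", "AUROC", "AUPRC", "TP", "TN", "FP", "FN",
            "Sen", "Spe", "F1", "Acc")
  rep$label <- rep$label[, cols]
  rep$thresholds <- thresholds
  rep$macro$auroc <- mean(rep$label$AUROC, na.rm = TRUE)
  rep$macro$auprc <- mean(rep$label$AUPRC, na.rm = TRUE)
  rep
}

#' Write an evaluation report to disk
#'
#' Serializes the macro/exam summaries as JSON and the per-label table as a
#' CSV mirroring the label-wise report columns.
#'
#' @param report a [metric_report()].
#' @param path output stem; writes `<path>.json` and `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report$label, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(macro = report$macro, exam = report$exam),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report:", nrow(x$label), "labels; macro F1 =",
      round(x$macro$f1, 4), "\n")
  invisible(x)
}
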