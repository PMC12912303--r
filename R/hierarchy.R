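#' Label hierarchy
#'
#' A label hierarchy is a rooted forest over diagnostic terms: every label
#' carries a level (1 = top level) and, for levels deeper than 1, a parent at
#' the previous level. Annotations over such a hierarchy are expected to form
#' complete ancestor chains (a positive child implies a positive parent).
#'
#' @param label character vector of label identifiers (unique, non-empty).
#' @param level integer vector of levels, 1 for roots.
#' @param parent character vector of parent labels; `NA` for roots.
#' @return A `label_hierarchy`: a data.frame with columns `label`, `level`,
#'   `parent`, validated so that each parent sits exactly one level above its
#'   children and the parent links are acyclic.
#' @export
label_hierarchy <- function(label, level, parent) {
  label <- as.character(label)
  level <- as.integer(level)
  parent <- as.character(parent)
  if (anyDuplicated(label)) stop("duplicate labels in hierarchy")
  if (length(level) != length(label) || length(parent) != length(label))
    stop("label, level, parent must have equal length")
  if (any(is.na(level)) || any(level < 1L)) stop("levels must be integers >= 1")
  is_root <- is.na(parent)
  if (any(level == 1L & !is_root))
    stop("level-1 labels must have no parent")
  if (any(!is_root & !(parent %in% label)))
    stop("unknown parent label(s): ",
         paste(setdiff(parent[!is_root], label), collapse = ", "))
  pl <- level[match(parent, label)]
  bad <- !is_root & (pl != level - 1L)
  if (any(bad))
    stop("parent must be one level above child; offending: ",
         paste(label[bad], collapse = ", "))
  h <- data.frame(label = label, level = level, parent = parent,
                  stringsAsFactors = FALSE)
  class(h) <- c("label_hierarchy", "data.frame")
  h
}

#' Ancestor chain of a label
#'
#' @param hierarchy a [label_hierarchy()].
#' @param label a single label.
#' @return Character vector of strict ancestors, nearest first.
#' @export
ancestors <- function(hierarchy, label) {
  out <- character(0)
  cur <- hierarchy$parent[match(label, hierarchy$label)]
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- hierarchy$parent[match(cur, hierarchy$label)]
  }
  out
}

#' Binary annotation matrix with co-occurrence statistics
#'
#' Wraps a records-by-labels binary matrix together with the counts the
#' correlation matrices are built from: the total record count N, per-label
#' positive counts N_i, and the symmetric co-occurrence matrix N_ij (number of
#' records positive for both i and j; its diagonal equals N_i).
#'
#' @param values binary matrix, records in rows, labels in columns
#'   (column names are the label identifiers).
#' @return An `annotation_matrix` list with elements `values`, `N`, `N_i`,
#'   `N_ij`.
#' @export
annotation_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("annotation matrix needs label column names")
  if (!all(values %in% c(0, 1))) stop("annotation matrix must be binary")
  storage.mode(values) <- "double"
  Nij <- crossprod(values)            # t(V) %*% V: co-occurrence counts
  obj <- list(values = values, N = nrow(values),
              N_i = diag(Nij), N_ij = Nij)
  names(obj$N_i) <- colnames(values)
  class(obj) <- "annotation_matrix"
  obj
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("annotation_matrix:", x$N, "records x", ncol(x$values), "labels;",
      "positives per label in [", min(x$N_i), ",", max(x$N_i), "]\n")
  invisible(x)
}

#' Drop labels with too few positive records
#'
#' Labels whose positive count falls below `min_positives` are removed from
#' both the annotation matrix and the hierarchy (the study protocol keeps
#' labels with more than 50 positives). Children of a removed parent become
#' roots of their own subtree (their parent link is cleared).
#'
#' @param ann an [annotation_matrix()].
#' @param hierarchy a [label_hierarchy()] over the same labels.
#' @param min_positives minimum positive count to retain a label (>= 1).
#' @return list with elements `annotations` and `hierarchy`, filtered
#'   consistently.
#' @export
filter_rare_labels <- function(ann, hierarchy, min_positives = 50) {
  stopifnot(inherits(ann, "annotation_matrix"))
  if (!is.numeric(min_positives) || min_positives < 1)
    stop("min_positives must be >= 1")
  keep <- names(ann$N_i)[ann$N_i >= min_positives]
  if (length(keep) == 0)
    stop("no label has at least ", min_positives, " positive records")
  values <- ann$values[, keep, drop = FALSE]
  h <- hierarchy[hierarchy$label %in% keep, , drop = FALSE]
  # a removed parent orphans its children: they become subtree roots
  h$parent[!is.na(h$parent) & !(h$parent %in% keep)] <- NA_character_
  rownames(h) <- NULL
  class(h) <- c("label_hierarchy", "data.frame")
  list(annotations = annotation_matrix(values), hierarchy = h)
}

#' Build the conditional, mutually exclusive and mutually symbiotic matrices
#'
#' From the annotation counts, the conditional-probability matrix is
#' `R[i, j] = N_ij / N_j`: the probability that a record known to carry label
#' j also carries label i. Two labels are mutually exclusive when they never
#' co-occur (`R_ME[i, j] = 1` iff `N_ij = 0`) and mutually symbiotic when
#' every record with j also has i (`R_MS[i, j] = 1` iff `N_ij = N_j`, i != j)
#' — i is then an ancestor of j in the data-driven sense. Both binary
#' matrices use exact integer tests, never float tolerances, and exclude
#' self-pairs.
#'
#' @param ann an [annotation_matrix()] with every `N_i > 0`.
#' @return A `correlation_set`: list with `R`, `R_ME`, `R_MS` (labels x
#'   labels), and `exclusive_count` (per-label number of exclusive partners).
#' @export
build_correlation_set <- function(ann) {
  stopifnot(inherits(ann, "annotation_matrix"))
  if (any(ann$N_i == 0))
    stop("labels with zero positives: ",
         paste(names(ann$N_i)[ann$N_i == 0], collapse = ", "),
         "; run filter_rare_labels() first")
  R <- sweep(ann$N_ij, 2, ann$N_i, "/")
  R_ME <- (ann$N_ij == 0) * 1
  R_MS <- (sweep(ann$N_ij, 2, ann$N_i, "==")) * 1
  diag(R_ME) <- 0
  diag(R_MS) <- 0
  cs <- list(R = R, R_ME = R_ME, R_MS = R_MS,
             exclusive_count = rowSums(R_ME))
  class(cs) <- "correlation_set"
  cs
}

#' @export
print.correlation_set <- function(x, ...) {
  cat("correlation_set over", nrow(x$R), "labels:",
      sum(x$R_ME) / 2, "exclusive pairs,", sum(x$R_MS), "symbiotic pairs\n")
  invisible(x)
}

#' Labels without any mutually exclusive partner
#'
#' Local softmax normalizes each label against its mutually exclusive set, so
#' a label with no exclusive partner has nothing to compete with and its
#' activation saturates. This diagnostic returns the offending labels; an
#' empty result means local softmax is applicable everywhere. The remedy is
#' [add_other_class()], which appends an artificial class exclusive to all.
#'
#' @param cs a [build_correlation_set()] result.
#' @return Character vector of labels with no exclusive partner.
#' @export
validate_exclusive_coverage <- function(cs) {
  names(cs$exclusive_count)[cs$exclusive_count == 0]
}

#' Append an artificial "other" class exclusive to every label
#'
#' Extends a correlation set with one extra class that is mutually exclusive
#' with every existing label (and symbiotic with none), so that local softmax
#' has a competitor for every class. The extra class carries no annotation
#' target; it only participates in the local-softmax denominators.
#'
#' @param cs a [build_correlation_set()] result.
#' @param name name of the artificial class.
#' @return The augmented `correlation_set`.
#' @export
add_other_class <- function(cs, name = "other") {
  labs <- rownames(cs$R)
  if (name %in% labs) stop("label '", name, "' already present")
  C <- length(labs)
  pad <- function(M, fill) {
    M2 <- rbind(cbind(M, rep(fill[1], C)), c(rep(fill[1], C), fill[2]))
    rownames(M2) <- colnames(M2) <- c(labs, name)
    M2
  }
  R <- pad(cs$R, c(0, 1))
  R_ME <- pad(cs$R_ME, c(1, 0))
  R_MS <- pad(cs$R_MS, c(0, 0))
  out <- list(R = R, R_ME = R_ME, R_MS = R_MS,
              exclusive_count = rowSums(R_ME))
  class(out) <- "correlation_set"
  out
}

#' Read annotations from CSV
#'
#' Two layouts are accepted: a dense binary matrix (first column `record_id`,
#' remaining columns one per label, values 0/1), or a sparse two-column
#' layout (`record_id`, `labels`) where `labels` is a semicolon-separated
#' list of positive labels.
#'
#' @param path CSV file.
#' @param labels for the sparse layout, the full ordered label set; defaults
#'   to the sorted union of observed labels.
#' @return An [annotation_matrix()].
#' @export
read_annotations <- function(path, labels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) == 2 && identical(names(df)[2], "labels")) {
    lst <- strsplit(df$labels, ";", fixed = TRUE)
    lst <- lapply(lst, function(x) x[nzchar(x)])
    if (is.null(labels)) labels <- sort(unique(unlist(lst)))
    V <- matrix(0, nrow(df), length(labels),
                dimnames = list(df$record_id, labels))
    for (r in seq_along(lst)) {
      unknown <- setdiff(lst[[r]], labels)
      if (length(unknown))
        stop("record ", df$record_id[r], " has unknown label(s): ",
             paste(unknown, collapse = ", "))
      V[r, lst[[r]]] <- 1
    }
  } else {
    V <- as.matrix(df[, -1, drop = FALSE])
    rownames(V) <- df[[1]]
    if (!all(V %in% c(0, 1))) stop("dense annotation CSV must be binary")
  }
  annotation_matrix(V)
}

#' Read a hierarchy table from CSV or JSON
#'
#' Expects columns/fields `label`, `level`, `parent` (empty or null parent
#' for roots).
#'
#' @param path CSV or JSON file.
#' @return A [label_hierarchy()].
#' @export
read_hierarchy <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  p <- as.character(df$parent)
  p[!is.na(p) & p == ""] <- NA_character_
  label_hierarchy(df$label, df$level, p)
}

#' Persist the three correlation matrices as labelled CSVs
#'
#' Writes `R.csv`, `R_ME.csv`, `R_MS.csv` under `dir`, row label i by column
#' label j, value `R[i, j]`.
#'
#' @param cs a correlation set.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_correlation_set <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("R", "R_ME", "R_MS"))
    utils::write.csv(cs[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Read correlation matrices written by [write_correlation_set()]
#' @param dir directory containing `R.csv`, `R_ME.csv`, `R_MS.csv`.
#' @return A `correlation_set`.
#' @export
read_correlation_set <- function(dir) {
  rd <- function(nm) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                   row.names = 1, check.names = FALSE))
    m
  }
  cs <- list(R = rd("R"), R_ME = rd("R_ME"), R_MS = rd("R_MS"))
  cs$exclusive_count <- rowSums(cs$R_ME)
  class(cs) <- "correlation_set"
  cs
}
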