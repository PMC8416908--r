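## Core typed containers: count matrix, covariate matrix, label vector.
## Plain S3 on top of base matrices; constructors enforce the invariants.

#' Construct a count matrix (genes x samples)
#'
#' Canonical container for RNA-seq read counts: genes in rows, samples in
#' columns, all entries non-negative integers.
#'
#' @param counts numeric matrix, genes x samples, non-negative integer-valued.
#' @param gene_ids character vector of unique gene identifiers (rows).
#'   Defaults to `rownames(counts)`.
#' @param sample_ids character vector of unique sample identifiers (columns).
#'   Defaults to `colnames(counts)`.
#' @return A `count_matrix` object (a matrix with class attribute).
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("count_matrix: gene_ids and sample_ids are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(counts)) {
    stop("count_matrix: gene_ids length != number of rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(counts)) {
    stop("count_matrix: sample_ids length != number of columns", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("count_matrix: duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("count_matrix: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  .check_counts_integer(counts, gene_ids, sample_ids)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(counts, class = c("count_matrix", "matrix", "array"))
}

# validation error naming the first offending cell
.check_counts_integer <- function(counts, gene_ids, sample_ids) {
  bad <- !is.finite(counts) | counts < 0 | (counts != round(counts))
  if (any(bad)) {
    idx <- which(bad)[1L]
    g <- gene_ids[(idx - 1L) %% nrow(counts) + 1L]
    s <- sample_ids[(idx - 1L) %/% nrow(counts) + 1L]
    stop(sprintf(
      "count_matrix: invalid count %s at gene '%s', sample '%s' (must be a non-negative integer)",
      format(counts[idx]), g, s), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  total reads: %s; zero fraction: %.3f\n",
              format(sum(x), big.mark = ","), mean(x == 0)))
  invisible(x)
}

#' Construct a covariate matrix (samples x features)
#'
#' Continuous per-sample covariates (e.g. radiomics volume ratios).  All
#' entries must be finite.  If `add_intercept` is `TRUE` a leading all-ones
#' `"(Intercept)"` column is prepended (unless one is already present).
#'
#' @param values numeric matrix or data.frame, samples x features.
#' @param sample_ids character vector of unique sample ids; defaults to
#'   `rownames(values)`.
#' @param feature_names character vector of unique feature names; defaults to
#'   `colnames(values)`.
#' @param add_intercept logical; prepend an all-ones intercept column.
#' @return A `covariate_matrix` object with attribute `has_intercept`.
#' @export
covariate_matrix <- function(values, sample_ids = rownames(values),
                             feature_names = colnames(values),
                             add_intercept = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    stop("covariate_matrix: sample_ids are required", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  if (is.null(feature_names)) {
    feature_names <- paste0("X", seq_len(ncol(values)))
  }
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != nrow(values) ||
      length(feature_names) != ncol(values)) {
    stop("covariate_matrix: id/name lengths do not match matrix shape",
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids) || anyDuplicated(feature_names)) {
    stop("covariate_matrix: duplicate sample ids or feature names",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    idx <- which(!is.finite(values))[1L]
    stop(sprintf("covariate_matrix: non-finite value at sample '%s', feature '%s'",
                 sample_ids[(idx - 1L) %% nrow(values) + 1L],
                 feature_names[(idx - 1L) %/% nrow(values) + 1L]),
         call. = FALSE)
  }
  has_intercept <- length(feature_names) > 0L &&
    feature_names[1L] == "(Intercept)" && all(values[, 1L] == 1)
  if (add_intercept && !has_intercept) {
    values <- cbind(1, values)
    feature_names <- c("(Intercept)", feature_names)
    has_intercept <- TRUE
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(values, has_intercept = has_intercept,
            class = c("covariate_matrix", "matrix", "array"))
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("covariate_matrix: %d samples x %d features%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "has_intercept"))) " (incl. intercept)" else ""))
  invisible(x)
}

#' Construct a label vector
#'
#' Per-sample class labels over an ordered class set of size `C >= 2`.  The
#' class order is significant: it fixes tie-breaking at prediction time and
#' the default positive class in binary evaluation.
#'
#' @param labels character vector (or factor) of class labels, one per sample.
#' @param sample_ids character vector of unique sample ids.
#' @param class_set optional ordered character vector of the declared classes;
#'   defaults to the sorted unique labels.
#' @return A `label_vector` object: a named factor with levels = class set.
#' @export
label_vector <- function(labels, sample_ids, class_set = NULL) {
  sample_ids <- as.character(sample_ids)
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids)) {
    stop("label_vector: labels and sample_ids lengths differ", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("label_vector: duplicate sample ids", call. = FALSE)
  }
  if (is.null(class_set)) class_set <- sort(unique(labels))
  class_set <- as.character(class_set)
  if (length(class_set) < 2L) {
    stop("label_vector: need at least 2 classes", call. = FALSE)
  }
  unknown <- setdiff(labels, class_set)
  if (length(unknown)) {
    stop("label_vector: labels outside the declared class set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  f <- factor(labels, levels = class_set)
  names(f) <- sample_ids
  structure(f, class = c("label_vector", "factor"))
}

#' @export
print.label_vector <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = seq_along(levels(x)),
                      labels = levels(x)))
  cat(sprintf("label_vector: %d samples, %d classes\n", length(x),
              nlevels(x)))
  print(tab)
  invisible(x)
}

# every declared class must be present before fitting
.require_all_classes <- function(labels, min_per_class = 1L) {
  tab <- table(labels)
  if (any(tab < min_per_class)) {
    stop(sprintf("class(es) with fewer than %d sample(s): %s", min_per_class,
                 paste(names(tab)[tab < min_per_class], collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Align counts, covariates and labels on shared samples
#'
#' Restricts all three inputs to the intersection of their sample ids, in the
#' order the ids appear in `counts`, and reports dropped ids via a message.
#' Idempotent: aligning an aligned triple changes nothing.
#'
#' @param counts a [count_matrix()].
#' @param covars a [covariate_matrix()].
#' @param labels a [label_vector()].
#' @return list with elements `counts`, `covars`, `labels`, `dropped` (named
#'   list of ids dropped from each input).
#' @export
align_dataset <- function(counts, covars, labels) {
  ids_counts <- colnames(counts)
  ids_cov <- rownames(covars)
  ids_lab <- names(labels)
  shared <- intersect(intersect(ids_counts, ids_cov), ids_lab)
  if (length(shared) == 0L) {
    stop("align_dataset: no samples shared between counts, covariates and labels",
         call. = FALSE)
  }
  shared <- ids_counts[ids_counts %in% shared]  # counts order is canonical
  dropped <- list(counts = setdiff(ids_counts, shared),
                  covars = setdiff(ids_cov, shared),
                  labels = setdiff(ids_lab, shared))
  n_drop <- sum(lengths(dropped))
  if (n_drop > 0L) {
    message(sprintf("align_dataset: dropped %d sample id(s): %s", n_drop,
                    paste(unique(unlist(dropped)), collapse = ", ")))
  }
  lab_sub <- labels[shared]
  list(
    counts = count_matrix(unclass(counts)[, shared, drop = FALSE]),
    covars = covariate_matrix(unclass(covars)[shared, , drop = FALSE]),
    labels = label_vector(as.character(lab_sub), shared, levels(labels)),
    dropped = dropped
  )
}
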