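## Delimited-text readers/writers and the versioned model container.
## TSV vs CSV is sniffed from the file extension (.tsv/.tab -> tab).

.sep_for <- function(path) {
  if (grepl("\\.(tsv|tab)(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
}

.read_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  utils::read.table(path, header = TRUE, sep = .sep_for(path),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "")
}

#' Read a count matrix from delimited text
#'
#' Expects one header row and one leading id column.  TSV or CSV, decided by
#' extension.  The result is always in canonical genes x samples orientation.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path,
                              orientation = c("genes_in_rows",
                                              "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- .read_table(path)
  if (ncol(df) < 2L) stop("count table needs an id column plus data", call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop("count table contains non-numeric cells", call. = FALSE)
  }
  if (orientation == "samples_in_rows") {
    m <- t(m)
    count_matrix(m, gene_ids = rownames(m), sample_ids = ids)
  } else {
    count_matrix(m, gene_ids = ids, sample_ids = colnames(m))
  }
}

#' Write a count matrix to delimited text
#'
#' @param x a [count_matrix()].
#' @param path output path; `.tsv` writes tab-separated, else comma.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a covariate matrix (samples in rows) from delimited text
#'
#' First column holds sample ids; remaining columns are continuous features.
#'
#' @inheritParams read_count_matrix
#' @param add_intercept prepend an all-ones intercept column.
#' @return A [covariate_matrix()].
#' @export
read_covariate_matrix <- function(path, add_intercept = FALSE) {
  df <- .read_table(path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  covariate_matrix(m, sample_ids = ids, feature_names = colnames(m),
                   add_intercept = add_intercept)
}

#' Write a covariate matrix to delimited text
#' @param x a [covariate_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariate_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read per-sample labels from delimited text
#'
#' First column holds sample ids; `label_col` (default: second column) holds
#' the class labels.  Additional columns (e.g. a grouping variable such as
#' gender) are preserved in the `extra` attribute.
#'
#' @inheritParams read_count_matrix
#' @param label_col name or index of the label column (default 2).
#' @param class_set optional ordered class set.
#' @return A [label_vector()]; extra columns in `attr(x, "extra")`.
#' @export
read_label_vector <- function(path, label_col = 2L, class_set = NULL) {
  df <- .read_table(path)
  ids <- as.character(df[[1L]])
  lv <- label_vector(df[[label_col]], ids, class_set)
  extra_cols <- setdiff(seq_len(ncol(df)),
                        c(1L, if (is.numeric(label_col)) label_col
                          else match(label_col, names(df))))
  if (length(extra_cols)) {
    extra <- df[, extra_cols, drop = FALSE]
    rownames(extra) <- ids
    attr(lv, "extra") <- extra
  }
  lv
}

#' Write labels to delimited text
#' @param labels a [label_vector()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_vector <- function(labels, path) {
  df <- data.frame(sample_id = names(labels),
                   label = as.character(labels))
  utils::write.table(df, path, sep = .sep_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## ---- model serialization ---------------------------------------------------
## Versioned, human-inspectable JSON container; numbers written at full
## precision so that load(save(m)) round-trips within 1e-15.

.MODEL_SCHEMA <- "nbfusion_model/1"

#' Save a fitted model to a versioned text container
#'
#' JSON with a schema tag; diff-able and human-inspectable.
#'
#' @param model an `nb_class_model` as returned by [fit_radiogenomics_nb()] or
#'   [fit_nblda()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "nb_class_model"))
  payload <- list(
    schema = .MODEL_SCHEMA,
    kind = model$kind,
    gene_ids = model$gene_ids,
    class_set = model$class_set,
    feature_names = model$feature_names,
    dispersions = as.numeric(model$dispersions),
    betas = if (is.null(model$betas)) NULL else
      lapply(model$betas, function(b) list(dim = dim(b), data = as.numeric(b))),
    lambda_rates = if (is.null(model$lambda_rates)) NULL else
      list(dim = dim(model$lambda_rates), data = as.numeric(model$lambda_rates)),
    priors = as.numeric(model$priors),
    fit_metadata = model$fit_metadata
  )
  # 17 significant digits make the decimal text round-trip IEEE-exact
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from disk
#'
#' @param path path written by [save_model()].
#' @return An `nb_class_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop(sprintf("load_model: corrupted payload in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
                      })
  if (is.null(payload$schema) || !identical(payload$schema, .MODEL_SCHEMA)) {
    stop(sprintf("load_model: schema mismatch (found '%s', expected '%s')",
                 if (is.null(payload$schema)) "<none>" else payload$schema,
                 .MODEL_SCHEMA), call. = FALSE)
  }
  genes <- payload$gene_ids
  classes <- payload$class_set
  feats <- payload$feature_names
  betas <- NULL
  if (!is.null(payload$betas)) {
    betas <- lapply(payload$betas, function(b) {
      m <- matrix(as.numeric(b$data), nrow = b$dim[1L], ncol = b$dim[2L])
      dimnames(m) <- list(feats, genes)
      m
    })
    names(betas) <- classes
  }
  lambda_rates <- NULL
  if (!is.null(payload$lambda_rates)) {
    lr <- payload$lambda_rates
    lambda_rates <- matrix(as.numeric(lr$data), nrow = lr$dim[1L],
                           ncol = lr$dim[2L], dimnames = list(genes, classes))
  }
  new_nb_class_model(
    kind = payload$kind,
    gene_ids = genes,
    class_set = classes,
    feature_names = feats,
    dispersions = stats::setNames(as.numeric(payload$dispersions), genes),
    betas = betas,
    lambda_rates = lambda_rates,
    priors = stats::setNames(as.numeric(payload$priors), classes),
    fit_metadata = payload$fit_metadata
  )
}
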