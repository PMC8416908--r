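## Confusion-matrix metrics, the repeated stratified 80/20 holdout protocol,
## group-stratified reports and a one-way ANOVA helper.

#' Tally a binary confusion matrix
#'
#' @param labels_true true labels (character/factor).
#' @param labels_pred predicted labels.
#' @param positive_class the class counted as positive.
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(labels_true, labels_pred, positive_class) {
  labels_true <- as.character(labels_true)
  labels_pred <- as.character(labels_pred)
  if (length(labels_true) != length(labels_pred)) {
    stop("confusion: label vectors have different lengths", call. = FALSE)
  }
  known <- union(unique(labels_true), positive_class)
  bad <- setdiff(labels_pred, known)
  if (length(bad)) {
    stop("confusion: unknown predicted label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tp <- sum(labels_true == positive_class & labels_pred == positive_class)
  fp <- sum(labels_true != positive_class & labels_pred == positive_class)
  fn <- sum(labels_true == positive_class & labels_pred != positive_class)
  tn <- sum(labels_true != positive_class & labels_pred != positive_class)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' Performance metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(FP+TN)`, PPV `TP/(TP+FP)`, NPV `TN/(FN+TN)`, balanced accuracy
#' `(sensitivity+specificity)/2` and F1 `TP/(TP+(FP+FN)/2)`.  Any metric with
#' a zero denominator is reported as `NA` (undefined), never silently zeroed.
#'
#' @param cm a `confusion_counts` from [confusion()].
#' @return named numeric vector of the seven metrics (NA where undefined).
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$TP; fp <- cm$FP; fn <- cm$FN; tn <- cm$TN
  total <- tp + fp + fn + tn
  if (total <= 0) stop("metrics_from_confusion: empty confusion matrix",
                       call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, fp + tn)
  c(accuracy = div(tp + tn, total),
    sensitivity = sens,
    specificity = spec,
    ppv = div(tp, tp + fp),
    npv = div(tn, fn + tn),
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                        else (sens + spec) / 2,
    f1 = div(tp, tp + (fp + fn) / 2))
}

#' Deterministic stratified train/test split
#'
#' Per-class training counts use largest-remainder rounding of
#' `train_fraction * n_c` (ties by class order), so class proportions in the
#' training split match the global proportions within one sample.
#'
#' @param labels a [label_vector()].
#' @param train_fraction fraction of samples per class assigned to training.
#' @param seed integer seed for the within-class shuffles.
#' @return list with character vectors `train` and `test` of sample ids.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("stratified_split: train_fraction must lie in (0, 1)", call. = FALSE)
  }
  .require_all_classes(labels, 2L)
  cls <- levels(labels)
  raw <- vapply(cls, function(cl) sum(labels == cl) * train_fraction,
                numeric(1))
  n_train <- floor(raw)
  remainder <- raw - n_train
  n_total_train <- round(sum(raw))
  extra <- n_total_train - sum(n_train)
  if (extra > 0) {
    give <- order(-remainder, seq_along(cls))[seq_len(extra)]
    n_train[give] <- n_train[give] + 1L
  }
  # every class keeps at least 1 training and 1 test sample
  for (i in seq_along(cls)) {
    n_c <- sum(labels == cls[i])
    n_train[i] <- min(max(n_train[i], 1L), n_c - 1L)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  train <- character(0)
  for (i in seq_along(cls)) {
    ids <- names(labels)[labels == cls[i]]
    train <- c(train, sample(ids, n_train[i]))
  }
  all_ids <- names(labels)
  list(train = all_ids[all_ids %in% train],
       test = setdiff(all_ids, train))
}

.subset_triple <- function(counts, covars, labels, ids) {
  list(counts = count_matrix(unclass(counts)[, ids, drop = FALSE]),
       covars = if (is.null(covars)) NULL else
         covariate_matrix(unclass(covars)[ids, , drop = FALSE]),
       labels = label_vector(as.character(labels[ids]), ids, levels(labels)))
}

#' Repeated stratified holdout evaluation
#'
#' The full protocol: for each repeat `r`, split stratified by label with seed
#' `base_seed + r`, fit on the training split (including the per-split gene
#' ranking, so panel selection never sees test data), predict the test split,
#' and compute confusion-matrix metrics.  The positive class defaults to the
#' first class in the declared class order.
#'
#' @param counts,covars,labels aligned dataset ([align_dataset()]);
#'   `covars` may be `NULL` for `method = "nblda"`.
#' @param method `"radiogenomics_nb"` or `"nblda"`.
#' @param config a [training_config()].
#' @param repeats number of independent splits (the study protocol uses 100).
#' @param train_fraction training fraction per class (default 0.8).
#' @param base_seed integer; repeat `r` uses seed `base_seed + r`.
#' @param positive_class class treated as positive; default first class.
#' @return An `evaluation_report`: `per_repeat` data.frame (one metric row per
#'   repeat), `summary` (mean and sd per metric over defined values, plus the
#'   count of undefined values), and `protocol` metadata.
#' @export
repeated_holdout <- function(counts, covars, labels,
                             method = c("radiogenomics_nb", "nblda"),
                             config = training_config(), repeats = 100L,
                             train_fraction = 0.8, base_seed = 0L,
                             positive_class = NULL) {
  method <- match.arg(method)
  if (repeats < 1) stop("repeated_holdout: repeats must be >= 1", call. = FALSE)
  if (method == "radiogenomics_nb" && is.null(covars)) {
    stop("repeated_holdout: covariates required for radiogenomics_nb",
         call. = FALSE)
  }
  if (is.null(positive_class)) positive_class <- levels(labels)[1L]
  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                    "balanced_accuracy", "f1")
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    seed_r <- base_seed + r
    sp <- stratified_split(labels, train_fraction, seed = seed_r)
    tr <- .subset_triple(counts, covars, labels, sp$train)
    te <- .subset_triple(counts, covars, labels, sp$test)
    cfg <- config
    cfg$seed <- seed_r
    if (method == "radiogenomics_nb") {
      model <- fit_radiogenomics_nb(tr$counts, tr$covars, tr$labels, cfg)
      pred <- predict_radiogenomics_nb(model, te$counts, te$covars)
    } else {
      model <- fit_nblda(tr$counts, tr$labels, cfg)
      pred <- predict_nblda(model, te$counts)
    }
    cm <- confusion(as.character(te$labels), as.character(pred$predicted),
                    positive_class)
    rows[[r]] <- c(repeat_id = r, seed = seed_r,
                   metrics_from_confusion(cm),
                   TP = cm$TP, FP = cm$FP, FN = cm$FN, TN = cm$TN)
  }
  per_repeat <- as.data.frame(do.call(rbind, rows))
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m)
      mean(per_repeat[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_names, function(m)
      stats::sd(per_repeat[[m]], na.rm = TRUE), numeric(1)),
    n_undefined = vapply(metric_names, function(m)
      sum(is.na(per_repeat[[m]])), numeric(1)),
    row.names = NULL
  )
  structure(list(
    per_repeat = per_repeat,
    summary = summary,
    protocol = list(method = method, repeats = repeats,
                    train_fraction = train_fraction, base_seed = base_seed,
                    positive_class = positive_class, k = config$k,
                    q = config$q, prior = config$prior)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %s, %d repeats (train fraction %.2f)\n",
              x$protocol$method, x$protocol$repeats,
              x$protocol$train_fraction))
  print(transform(x$summary, mean = round(mean, 4), sd = round(sd, 4)))
  invisible(x)
}

#' Write an evaluation report to CSV + JSON
#'
#' Per-repeat rows go to `<stem>.csv`; the summary (means, sds, protocol,
#' seeds) to `<stem>.json`.
#'
#' @param report an `evaluation_report`.
#' @param stem output path stem (no extension).
#' @return character vector of the two paths, invisibly.
#' @export
write_report <- function(report, stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  utils::write.table(report$per_repeat, csv, sep = ",", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            protocol = report$protocol),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, json))
}

#' Independent evaluation per sample group
#'
#' Runs the full [repeated_holdout()] pipeline independently on each subset of
#' samples defined by `group` (e.g. gender).  Groups too small to stratify
#' (any class below 2 samples, or fewer than 4 samples overall) are skipped
#' with a warning.
#'
#' @inheritParams repeated_holdout
#' @param group per-sample category vector named by sample id (or in the
#'   order of `labels`).
#' @return named list of `evaluation_report`s, one per retained group.
#' @export
group_stratified_reports <- function(counts, covars, labels, group,
                                     method = c("radiogenomics_nb", "nblda"),
                                     config = training_config(),
                                     repeats = 100L, train_fraction = 0.8,
                                     base_seed = 0L, positive_class = NULL) {
  method <- match.arg(method)
  group <- as.character(group)
  if (is.null(names(group))) names(group) <- names(labels)
  group <- group[names(labels)]
  out <- list()
  for (gl in unique(group)) {
    ids <- names(labels)[group == gl]
    sub_lab <- labels[ids]
    tab <- table(sub_lab)
    if (length(ids) < 4L || any(tab < 2L)) {
      warning(sprintf("group_stratified_reports: group '%s' too small; skipped",
                      gl))
      next
    }
    sub <- .subset_triple(counts, covars, labels, ids)
    out[[gl]] <- repeated_holdout(sub$counts, sub$covars, sub$labels,
                                  method = method, config = config,
                                  repeats = repeats,
                                  train_fraction = train_fraction,
                                  base_seed = base_seed,
                                  positive_class = positive_class)
  }
  out
}

#' One-way fixed-effects ANOVA across methods' per-repeat metrics
#'
#' Compares per-repeat metric vectors (one vector per method) with a standard
#' one-way F test.  The repeated-split vectors violate the independence
#' assumption — this mirrors common practice and is documented as a caveat,
#' not corrected.  Degenerate inputs: all values identical across all groups
#' gives `F = 0, p = 1` with a warning; zero within-group variance with
#' between-group separation gives a capped `F` and `p = 0`.
#'
#' @param metric_vectors named list, method -> numeric vector (each length
#'   >= 2); `NA`s are dropped.
#' @return list with `F`, `p_value`, `df_between`, `df_within`.
#' @export
anova_compare <- function(metric_vectors) {
  if (length(metric_vectors) < 2L) {
    stop("anova_compare: need at least 2 methods", call. = FALSE)
  }
  vals <- lapply(metric_vectors, function(v) v[!is.na(v)])
  if (any(lengths(vals) < 2L)) {
    stop("anova_compare: each method needs at least 2 defined values",
         call. = FALSE)
  }
  x <- unlist(vals, use.names = FALSE)
  grp <- rep(seq_along(vals), lengths(vals))
  k <- length(vals)
  n <- length(x)
  grand <- mean(x)
  means <- vapply(split(x, grp), mean, numeric(1))
  ssb <- sum(lengths(vals) * (means - grand)^2)
  ssw <- sum((x - means[grp])^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ssw <= .Machine$double.eps * sum(x^2)) {
    if (ssb <= .Machine$double.eps * max(sum(x^2), 1)) {
      warning("anova_compare: all values identical; p = 1 by convention")
      return(list(F = 0, p_value = 1, df_between = df_b, df_within = df_w))
    }
    return(list(F = .Machine$double.xmax, p_value = 0,
                df_between = df_b, df_within = df_w))
  }
  f <- (ssb / df_b) / (ssw / df_w)
  list(F = f, p_value = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w)
}
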