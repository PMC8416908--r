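## The radiogenomics-NB classifier and the counts-only NBLDA baseline.
##
## Training pipeline (both): quantile filter -> likelihood-ratio gene ranking
## on the TRAINING data -> top-k panel -> class-wise size factors and means ->
## raw + shrunken dispersions -> class-conditional mean model -> priors.
## Radiogenomics-NB parameterizes the mean as exp(X beta_gc); NBLDA as
## s_t * lambda'_gc with no covariate link.

.MAX_TEST_COUNT <- 1e9

#' Training configuration
#'
#' @param k gene panel size (top-k of the ranking); default 10.
#' @param q quantile threshold for low-count filtering; default 0.25.
#' @param prior `"uniform"` (all classes equally likely, the default) or
#'   `"empirical"` (training class frequencies).
#' @param intercept prepend an all-ones intercept column to the covariates.
#' @param phi_bounds dispersion clip bounds.
#' @param seed integer recorded in the model metadata (fitting itself is
#'   deterministic; the seed documents the split that produced the data).
#' @param panel optional externally supplied character vector of gene ids,
#'   bypassing the internal ranking (required for more than 2 classes).
#' @return a `training_config` list.
#' @export
training_config <- function(k = 10L, q = 0.25,
                            prior = c("uniform", "empirical"),
                            intercept = TRUE, phi_bounds = c(1e-6, 1e3),
                            seed = NA_integer_, panel = NULL) {
  prior <- match.arg(prior)
  if (k < 1 || k != round(k)) stop("training_config: k must be >= 1", call. = FALSE)
  if (q < 0 || q > 1) stop("training_config: q must lie in [0, 1]", call. = FALSE)
  structure(list(k = as.integer(k), q = q, prior = prior,
                 intercept = isTRUE(intercept), phi_bounds = phi_bounds,
                 seed = seed, panel = panel),
            class = "training_config")
}

new_nb_class_model <- function(kind, gene_ids, class_set, feature_names,
                               dispersions, betas, lambda_rates, priors,
                               fit_metadata) {
  stopifnot(all(dispersions > 0),
            abs(sum(priors) - 1) < 1e-12,
            is.null(betas) || all(vapply(betas, function(b) all(is.finite(b)),
                                         logical(1))))
  structure(list(kind = kind, gene_ids = gene_ids, class_set = class_set,
                 feature_names = feature_names, dispersions = dispersions,
                 betas = betas, lambda_rates = lambda_rates, priors = priors,
                 fit_metadata = fit_metadata),
            class = "nb_class_model")
}

#' @export
print.nb_class_model <- function(x, ...) {
  cat(sprintf("nb_class_model (%s): %d-gene panel, classes: %s\n", x$kind,
              length(x$gene_ids), paste(x$class_set, collapse = " / ")))
  cat(sprintf("  dispersion range: [%.4g, %.4g]; priors: %s\n",
              min(x$dispersions), max(x$dispersions),
              paste(sprintf("%.3f", x$priors), collapse = ", ")))
  invisible(x)
}

.class_priors <- function(labels, mode) {
  cls <- levels(labels)
  if (mode == "uniform") {
    stats::setNames(rep(1 / length(cls), length(cls)), cls)
  } else {
    tab <- table(labels)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
}

# shared front half of both fits: filter, rank, panel, means, dispersions
.fit_shared <- function(counts, labels, config) {
  .require_all_classes(labels, 2L)
  filtered <- quantile_filter(counts, config$q)
  panel <- config$panel
  if (is.null(panel)) {
    if (nlevels(labels) != 2L) {
      stop("fit: internal gene ranking supports 2 classes; supply config$panel for more",
           call. = FALSE)
    }
    ranking <- rank_genes_lrt(filtered, labels)
    panel <- top_k_panel(ranking, config$k)
  } else {
    missing <- setdiff(panel, rownames(filtered))
    if (length(missing)) {
      stop("fit: supplied panel genes absent after filtering: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    panel <- panel[seq_len(min(config$k, length(panel)))]
  }
  if (length(panel) == 0L) stop("fit: empty gene panel", call. = FALSE)
  panel_counts <- count_matrix(unclass(filtered)[panel, , drop = FALSE])
  cm <- compute_class_means(panel_counts, labels)
  raw <- estimate_dispersion_raw(panel_counts, cm, labels)
  disp <- shrink_dispersion_wl(raw)
  list(panel = panel, panel_counts = panel_counts, class_means = cm,
       raw = raw, disp = disp)
}

.disp_metadata <- function(disp, config) {
  list(alpha = disp$alpha, phi0 = disp$phi0, tau0_sq = disp$tau0_sq,
       tau_sq = as.numeric(disp$tau_sq), k = config$k, q = config$q,
       prior = config$prior, intercept = config$intercept,
       seed = config$seed,
       config_hash = paste0("k", config$k, "_q", config$q, "_", config$prior,
                            "_i", as.integer(config$intercept)))
}

#' Fit the radiogenomics-NB classifier
#'
#' Trains the Bayes classifier whose class-conditional law for each panel gene
#' is NB with mean `exp(X_i beta_gc)` and shared gene-wise dispersion.  The
#' coefficients are estimated by regressing the log of the size-factor-based
#' fitted means on the covariates, separately per class.
#'
#' @param counts a [count_matrix()] (training samples).
#' @param covars a [covariate_matrix()] on the same samples.
#' @param labels a [label_vector()]; every class needs at least 2 samples.
#' @param config a [training_config()].
#' @return An `nb_class_model` of kind `"radiogenomics_nb"`.
#' @export
fit_radiogenomics_nb <- function(counts, covars, labels,
                                 config = training_config()) {
  if (!identical(colnames(counts), rownames(covars)) ||
      !identical(colnames(counts), names(labels))) {
    stop("fit_radiogenomics_nb: inputs not aligned; run align_dataset() first",
         call. = FALSE)
  }
  if (config$intercept && !isTRUE(attr(covars, "has_intercept"))) {
    covars <- covariate_matrix(unclass(covars), add_intercept = TRUE)
  }
  sh <- .fit_shared(counts, labels, config)
  cls <- levels(labels)
  X <- unclass(covars)
  betas <- lapply(cls, function(cl) {
    sel <- which(labels == cl)
    fit_beta(covariate_matrix(X[sel, , drop = FALSE]),
             sh$class_means$per_class[[cl]]$mu)$betas
  })
  names(betas) <- cls
  new_nb_class_model(
    kind = "radiogenomics_nb",
    gene_ids = sh$panel,
    class_set = cls,
    feature_names = colnames(X),
    dispersions = stats::setNames(sh$disp$phi_wl, sh$panel),
    betas = betas,
    lambda_rates = NULL,
    priors = .class_priors(labels, config$prior),
    fit_metadata = .disp_metadata(sh$disp, config)
  )
}

# Eq.-11-style per-class scores for an n x G count block given n x G means
.score_block <- function(Y, MU, phi, log_prior) {
  G <- length(phi)
  phim <- matrix(phi, nrow(Y), G, byrow = TRUE)
  rowSums(matrix(nb_log_pmf(as.numeric(Y), as.numeric(MU), as.numeric(phim)),
                 nrow(Y), G)) + log_prior
}

.predict_from_scores <- function(scores, class_set, sample_ids) {
  # scores: n x C matrix of log-joint values
  mx <- apply(scores, 1L, max)
  post <- exp(scores - mx)
  post <- post / rowSums(post)
  pred_idx <- apply(scores, 1L, which.max)  # ties -> first class in order
  colnames(scores) <- paste0("score_", class_set)
  colnames(post) <- paste0("posterior_", class_set)
  structure(
    data.frame(sample_id = sample_ids, scores, post,
               predicted = factor(class_set[pred_idx], levels = class_set),
               stringsAsFactors = FALSE, check.names = FALSE,
               row.names = NULL),
    class = c("prediction_result", "data.frame")
  )
}

.panel_test_counts <- function(model, test_counts) {
  missing <- setdiff(model$gene_ids, rownames(test_counts))
  if (length(missing)) {
    stop("predict: test counts lack panel gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Y <- t(unclass(test_counts)[model$gene_ids, , drop = FALSE])  # n x G
  if (any(Y > .MAX_TEST_COUNT)) {
    stop(sprintf("predict: test count exceeds %g (numeric guardrail)",
                 .MAX_TEST_COUNT), call. = FALSE)
  }
  Y
}

#' Predict class membership with a radiogenomics-NB model
#'
#' Per class, the score is the NB log-likelihood of the test counts with mean
#' `exp(X_t beta_gc)` plus the log prior; no test size factor enters because
#' the covariates carry the sample scale.  Posteriors are obtained by
#' log-sum-exp normalization; argmax ties break to the first class in the
#' declared class order.
#'
#' @param model an `nb_class_model` of kind `"radiogenomics_nb"`.
#' @param test_counts [count_matrix()] covering the model's gene panel.
#' @param test_covars [covariate_matrix()] with the model's feature names.
#' @return A `prediction_result` data.frame: per-class scores, posteriors
#'   (rows sum to 1), and `predicted`.
#' @export
predict_radiogenomics_nb <- function(model, test_counts, test_covars) {
  stopifnot(model$kind == "radiogenomics_nb")
  if (!identical(colnames(test_counts), rownames(test_covars))) {
    stop("predict_radiogenomics_nb: test counts/covariates sample order differs",
         call. = FALSE)
  }
  if ("(Intercept)" %in% model$feature_names &&
      !isTRUE(attr(test_covars, "has_intercept"))) {
    test_covars <- covariate_matrix(unclass(test_covars), add_intercept = TRUE)
  }
  if (!identical(colnames(test_covars), model$feature_names)) {
    stop("predict_radiogenomics_nb: covariate names do not match the model (",
         paste(model$feature_names, collapse = ", "), ")", call. = FALSE)
  }
  Y <- .panel_test_counts(model, test_counts)
  X <- unclass(test_covars)
  phi <- model$dispersions
  scores <- vapply(model$class_set, function(cl) {
    MU <- exp(X %*% model$betas[[cl]])  # n x G
    .score_block(Y, MU, phi, log(model$priors[[cl]]))
  }, numeric(nrow(Y)))
  scores <- matrix(scores, nrow = nrow(Y),
                   dimnames = list(NULL, model$class_set))
  .predict_from_scores(scores, model$class_set, colnames(test_counts))
}

#' Fit the counts-only NBLDA baseline
#'
#' Same pipeline as [fit_radiogenomics_nb()] but the class-conditional mean is
#' `mu_tgc = s_t * lambda'_gc`: a per-sample size factor times a per-gene
#' class rate, with no covariate link.  The stored rate `lambda'_gc` is the
#' class's per-gene read fraction scaled by the mean training-sample panel
#' total, so an average-depth sample has `s_t = 1`.
#'
#' @inheritParams fit_radiogenomics_nb
#' @return An `nb_class_model` of kind `"nblda"`.
#' @export
fit_nblda <- function(counts, labels, config = training_config()) {
  if (!identical(colnames(counts), names(labels))) {
    stop("fit_nblda: counts and labels not aligned", call. = FALSE)
  }
  sh <- .fit_shared(counts, labels, config)
  cls <- levels(labels)
  mean_total <- mean(colSums(unclass(sh$panel_counts)))
  lambda_rates <- vapply(cls, function(cl) {
    lam <- sh$class_means$per_class[[cl]]$lambda
    mean_total * lam / sum(lam)
  }, numeric(length(sh$panel)))
  lambda_rates <- matrix(lambda_rates, nrow = length(sh$panel),
                         dimnames = list(sh$panel, cls))
  md <- .disp_metadata(sh$disp, config)
  md$mean_train_total <- mean_total
  md$test_size_factor_rule <- "test_total / mean_train_total"
  new_nb_class_model(
    kind = "nblda",
    gene_ids = sh$panel,
    class_set = cls,
    feature_names = character(0),
    dispersions = stats::setNames(sh$disp$phi_wl, sh$panel),
    betas = NULL,
    lambda_rates = lambda_rates,
    priors = .class_priors(labels, config$prior),
    fit_metadata = md
  )
}

#' Predict class membership with an NBLDA model
#'
#' The test size factor is the test sample's panel total divided by the mean
#' training-sample panel total (floored at 0.5 reads to keep means positive).
#'
#' @param model an `nb_class_model` of kind `"nblda"`.
#' @param test_counts [count_matrix()] covering the model's gene panel.
#' @return A `prediction_result` data.frame.
#' @export
predict_nblda <- function(model, test_counts) {
  stopifnot(model$kind == "nblda")
  Y <- .panel_test_counts(model, test_counts)
  s_t <- pmax(rowSums(Y), 0.5) / model$fit_metadata$mean_train_total
  phi <- model$dispersions
  scores <- vapply(model$class_set, function(cl) {
    MU <- outer(s_t, model$lambda_rates[, cl])
    .score_block(Y, MU, phi, log(model$priors[[cl]]))
  }, numeric(nrow(Y)))
  scores <- matrix(scores, nrow = nrow(Y),
                   dimnames = list(NULL, model$class_set))
  .predict_from_scores(scores, model$class_set, colnames(test_counts))
}
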