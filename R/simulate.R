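## Synthetic data generator: draws exactly the statistical structure the
## classifier assumes — NB counts whose log-mean is linear in correlated
## continuous covariates, with gene-specific dispersions and class imbalance.
## NB sampling uses the gamma-Poisson mixture, the exact NB law for any
## real phi > 0.

#' Define a simulation scenario
#'
#' @param G number of genes.
#' @param n_per_class named integer vector of class sizes (names are the
#'   class labels, in declared order).
#' @param cov_mean covariate mean vector (length p), or a named list of one
#'   mean vector per class.
#' @param cov_sigma p x p covariate covariance matrix (symmetric PSD).
#' @param beta named list, one `(p+1) x G` coefficient matrix per class; first
#'   row is the intercept (gene baseline log-abundance), remaining rows the
#'   covariate slopes.
#' @param phi length-`G` vector of true dispersions (all > 0).
#' @param null_genes character vector of gene ids whose coefficients are equal
#'   across classes (bookkeeping only; stored in the truth record).
#' @param seed default RNG seed used by [generate_dataset()].
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(G, n_per_class, cov_mean, cov_sigma, beta, phi,
                          null_genes = character(0), seed = 1L) {
  p <- nrow(cov_sigma)
  stopifnot(isSymmetric(unname(cov_sigma)),
            all(eigen(cov_sigma, symmetric = TRUE,
                      only.values = TRUE)$values > -1e-10),
            all(phi > 0), length(phi) == G, all(n_per_class >= 1))
  classes <- names(n_per_class)
  if (is.null(classes)) stop("scenario_spec: n_per_class must be named",
                             call. = FALSE)
  stopifnot(identical(sort(names(beta)), sort(classes)))
  for (cl in classes) {
    stopifnot(nrow(beta[[cl]]) == p + 1L, ncol(beta[[cl]]) == G)
  }
  if (!is.list(cov_mean)) cov_mean <- stats::setNames(
    rep(list(cov_mean), length(classes)), classes)
  structure(list(G = G, n_per_class = n_per_class, p = p,
                 cov_mean = cov_mean, cov_sigma = cov_sigma, beta = beta,
                 phi = phi, null_genes = null_genes, seed = seed),
            class = "scenario_spec")
}

# multivariate normal draw via Cholesky (PSD handled by eigen fallback)
.rmvnorm <- function(n, mean, sigma) {
  p <- length(mean)
  L <- tryCatch(chol(sigma), error = function(e) {
    ev <- eigen(sigma, symmetric = TRUE)
    t(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors)))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2L, mean, "+")
}

#' Generate a synthetic dataset from a scenario
#'
#' Covariates are multivariate normal per class; counts are drawn NB with
#' mean `exp(X_i beta_gc)` and dispersion `phi_g` through the gamma-Poisson
#' mixture (`rate ~ Gamma(1/phi, scale = phi*mu)`, then Poisson).  Fully
#' reproducible from the seed.
#'
#' @param spec a [scenario_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param ordinal_features optional integer vector of covariate indices to
#'   threshold around their mean into 0/1 ordinal features after count
#'   generation (mimics mean-thresholded volume ratios).
#' @return list with `counts` ([count_matrix()]), `covars`
#'   ([covariate_matrix()], no intercept column), `labels`
#'   ([label_vector()]) and `truth` (all generating parameters).
#' @export
generate_dataset <- function(spec, seed = spec$seed, ordinal_features = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  classes <- names(spec$n_per_class)
  n <- sum(spec$n_per_class)
  gene_ids <- sprintf("gene%03d", seq_len(spec$G))
  sample_ids <- sprintf("s%04d", seq_len(n))
  labels <- rep(classes, times = spec$n_per_class)
  X <- matrix(NA_real_, n, spec$p)
  counts <- matrix(NA_real_, spec$G, n)
  offset <- 0L
  for (cl in classes) {
    n_c <- spec$n_per_class[[cl]]
    idx <- offset + seq_len(n_c)
    offset <- offset + n_c
    Xc <- .rmvnorm(n_c, spec$cov_mean[[cl]], spec$cov_sigma)
    X[idx, ] <- Xc
    eta <- cbind(1, Xc) %*% spec$beta[[cl]]  # n_c x G log-means
    if (any(eta > 30)) {
      stop("generate_dataset: linear predictor exceeds 30 (mean overflow); rescale covariates or coefficients",
           call. = FALSE)
    }
    mu <- exp(eta)
    phi <- matrix(spec$phi, n_c, spec$G, byrow = TRUE)
    lam <- matrix(stats::rgamma(n_c * spec$G, shape = 1 / phi,
                                scale = phi * mu), n_c, spec$G)
    counts[, idx] <- t(matrix(stats::rpois(n_c * spec$G, lam), n_c, spec$G))
  }
  if (!is.null(ordinal_features)) {
    for (j in ordinal_features) {
      X[, j] <- as.numeric(X[, j] > mean(X[, j]))
    }
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  dimnames(X) <- list(sample_ids,
                      sprintf("feature%02d", seq_len(spec$p)))
  truth <- list(beta = lapply(spec$beta, function(b) {
    dimnames(b) <- list(c("(Intercept)",
                          sprintf("feature%02d", seq_len(spec$p))), gene_ids)
    b
  }), phi = stats::setNames(spec$phi, gene_ids),
  null_genes = spec$null_genes, seed = seed,
  n_per_class = spec$n_per_class)
  list(counts = count_matrix(counts),
       covars = covariate_matrix(X),
       labels = label_vector(labels, sample_ids, classes),
       truth = truth)
}

# shared slope vectors make the size-factor moment estimator of mu_igc
# consistent for exp(X beta); see the methods vignette
.build_preset <- function(G, n_per_class, slopes, gap_genes, gap,
                          phi, cov_mean, cov_sigma, base_range = c(log(15), log(60)),
                          seed = 1L) {
  p <- length(slopes[[1L]])
  classes <- names(n_per_class)
  base <- seq(base_range[1L], base_range[2L], length.out = G)
  beta <- lapply(classes, function(cl) {
    b <- rbind(base, matrix(slopes[[cl]], p, G))
    b
  })
  names(beta) <- classes
  if (length(gap_genes)) {
    # differential genes alternate direction, as real DE panels do
    signs <- rep_len(c(1, -1), length(gap_genes))
    beta[[classes[2L]]][1L, gap_genes] <-
      beta[[classes[2L]]][1L, gap_genes] + gap * signs
  }
  null_genes <- sprintf("gene%03d", setdiff(seq_len(G), gap_genes))
  same_slopes <- identical(slopes[[1L]], slopes[[2L]])
  if (!same_slopes) null_genes <- character(0)
  scenario_spec(G = G, n_per_class = n_per_class, cov_mean = cov_mean,
                cov_sigma = cov_sigma, beta = beta,
                phi = if (length(phi) == 1L) rep(phi, G) else phi,
                null_genes = null_genes, seed = seed)
}

#' Built-in simulation scenarios
#'
#' * `well_separated` — 2 classes x 150 samples, 50 genes, half with a class
#'   log-mean gap of 1.5, dispersion 0.3, two correlated covariates acting as
#'   shared sample-scale modifiers.
#' * `null` — no class signal anywhere: chance-level classification.
#' * `covariate_only_signal` — identical per-gene baselines across classes and
#'   opposite-sign shared covariate slopes (+0.8 / -0.8) on a symmetric
#'   covariate: the marginal count law is the same in both classes (a
#'   counts-only classifier is at chance) while the count-covariate coupling
#'   carries the signal.
#' * `count_only_signal` — class gap in the gene baselines, zero covariate
#'   slopes.
#' * `idh_like_imbalance` — 85 vs 23 samples and 8 correlated volumetric-ratio
#'   style covariates, mirroring a mutant/wildtype marker imbalance.
#'
#' @param n_override optional named list, preset name -> per-class sample
#'   sizes, to rescale a preset (e.g. for recovery tests at larger n).
#' @return named list of [scenario_spec()] objects.
#' @export
preset_scenarios <- function(n_override = NULL) {
  sig2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  presets <- list(
    well_separated = .build_preset(
      G = 50L, n_per_class = c(classA = 150L, classB = 150L),
      slopes = list(classA = c(0.2, -0.1), classB = c(0.2, -0.1)),
      gap_genes = 26:50, gap = 1.5, phi = 0.3,
      cov_mean = c(0, 0), cov_sigma = sig2),
    null = .build_preset(
      G = 50L, n_per_class = c(classA = 60L, classB = 60L),
      slopes = list(classA = c(0.2, -0.1), classB = c(0.2, -0.1)),
      gap_genes = integer(0), gap = 0, phi = 0.3,
      cov_mean = c(0, 0), cov_sigma = sig2),
    covariate_only_signal = .build_preset(
      G = 40L, n_per_class = c(classA = 100L, classB = 100L),
      slopes = list(classA = c(0.8, 0), classB = c(-0.8, 0)),
      gap_genes = integer(0), gap = 0, phi = 0.3,
      cov_mean = c(0, 0), cov_sigma = diag(2)),
    count_only_signal = .build_preset(
      G = 40L, n_per_class = c(classA = 100L, classB = 100L),
      slopes = list(classA = c(0, 0), classB = c(0, 0)),
      gap_genes = 21:40, gap = 1.5, phi = 0.3,
      cov_mean = c(0, 0), cov_sigma = sig2),
    idh_like_imbalance = .build_preset(
      G = 100L, n_per_class = c(Mutant = 85L, WT = 23L),
      slopes = list(Mutant = c(0.3, rep(0.05, 7)),
                    WT = c(-0.3, rep(0.05, 7))),
      gap_genes = 61:100, gap = 1.0,
      phi = seq(0.2, 0.6, length.out = 100L),
      cov_mean = rep(0, 8), cov_sigma = 0.3^abs(outer(1:8, 1:8, "-")))
  )
  if (!is.null(n_override)) {
    for (nm in names(n_override)) {
      spec <- presets[[nm]]
      n_new <- n_override[[nm]]
      stopifnot(!is.null(spec), identical(names(n_new), names(spec$n_per_class)))
      spec$n_per_class <- n_new
      presets[[nm]] <- spec
    }
  }
  presets
}
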