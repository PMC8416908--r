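# Shared fixtures and independent oracles. All fixtures are built in code.

# tiny deterministic count matrix
toy_counts <- function(values = matrix(c(1, 3, 2, 4, 0, 5), nrow = 3,
                                       byrow = TRUE),
                       genes = paste0("g", seq_len(nrow(values))),
                       samples = paste0("s", seq_len(ncol(values)))) {
  count_matrix(values, gene_ids = genes, sample_ids = samples)
}

# random valid dataset for property loops
random_dataset <- function(G = 8, n = 10, seed = 1, C = 2) {
  set.seed(seed)
  m <- matrix(rpois(G * n, lambda = 20), G, n)
  counts <- count_matrix(m, gene_ids = sprintf("g%02d", 1:G),
                         sample_ids = sprintf("s%02d", 1:n))
  labels <- label_vector(rep(paste0("c", 1:C), length.out = n),
                         colnames(counts), paste0("c", 1:C))
  covars <- covariate_matrix(matrix(rnorm(n * 2), n, 2,
                                    dimnames = list(colnames(counts),
                                                    c("f1", "f2"))))
  list(counts = counts, covars = covars, labels = labels)
}

# independent NB log-pmf oracle (stats::dnbinom, size = 1/phi);
# vectorized over y/mu for scalar phi
oracle_nb_log_pmf <- function(y, mu, phi) {
  if (phi == 0) dpois(y, mu, log = TRUE)
  else dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
}
oracle_nb_log_pmf_vec <- oracle_nb_log_pmf

# hand-built small radiogenomics model (bypasses fitting)
small_random_model <- function(G = 5, p = 2, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", 1:G)
  feats <- c("(Intercept)", paste0("f", seq_len(p)))
  betas <- lapply(c(A = "A", B = "B"), function(cl) {
    b <- rbind(runif(G, 1.5, 3), matrix(rnorm(p * G, sd = 0.3), p, G))
    dimnames(b) <- list(feats, genes)
    b
  })
  nbfusion:::new_nb_class_model(
    kind = "radiogenomics_nb", gene_ids = genes, class_set = c("A", "B"),
    feature_names = feats,
    dispersions = setNames(runif(G, 0.1, 1), genes),
    betas = betas, lambda_rates = NULL,
    priors = c(A = 0.5, B = 0.5),
    fit_metadata = list(seed = seed))
}

# direct Bayes scoring oracle: per-gene dnbinom products in log domain
oracle_scores <- function(model, Y, X) {
  # Y: n x G counts, X: n x (p+1) covariates
  vapply(model$class_set, function(cl) {
    MU <- exp(X %*% model$betas[[cl]])
    s <- numeric(nrow(Y))
    for (i in seq_len(nrow(Y))) {
      for (g in seq_len(ncol(Y))) {
        s[i] <- s[i] + oracle_nb_log_pmf(Y[i, g], MU[i, g],
                                         model$dispersions[g])
      }
    }
    s + log(model$priors[[cl]])
  }, numeric(nrow(Y)))
}

# hand-constructed class_means with the per-sample means fixed externally
# (mu_mat: genes x samples, columns split by the labels)
make_class_means <- function(mu_mat, labels) {
  per_class <- lapply(levels(labels), function(cl) {
    mu <- mu_mat[, labels == cl, drop = FALSE]
    list(size_factors = setNames(rep(1 / ncol(mu), ncol(mu)), colnames(mu)),
         lambda = rowSums(mu), mu = mu)
  })
  names(per_class) <- levels(labels)
  structure(list(per_class = per_class, class_set = levels(labels),
                 gene_ids = rownames(mu_mat)), class = "class_means")
}

# split an aligned dataset by sample ids (mirrors the internal helper)
subset_ds <- function(ds, ids) {
  nbfusion:::.subset_triple(ds$counts, ds$covars, ds$labels, ids)
}
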