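test_that("scoring equals the brute-force Bayes oracle on small models", {
  for (s in 1:10) {
    model <- small_random_model(G = 5, p = 2, seed = 100 + s)
    set.seed(200 + s)
    n <- 6
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    colnames(X) <- model$feature_names
    rownames(X) <- sprintf("t%02d", 1:n)
    Y <- matrix(rpois(n * 5, 15), n, 5,
                dimnames = list(rownames(X), model$gene_ids))
    counts <- count_matrix(t(Y))
    covars <- covariate_matrix(X)
    pred <- predict_radiogenomics_nb(model, counts, covars)

    expected <- oracle_scores(model, Y, X)
    got <- as.matrix(pred[, paste0("score_", model$class_set)])
    expect_equal(unname(got), unname(expected), tolerance = 1e-10)
    # posterior normalization
    post <- as.matrix(pred[, paste0("posterior_", model$class_set)])
    expect_equal(unname(rowSums(post)), rep(1, n), tolerance = 1e-9)
    # argmax agreement
    expect_identical(as.integer(pred$predicted),
                     unname(apply(expected, 1, which.max)))
  }
})

test_that("symmetric models tie, and ties break to the first declared class", {
  model <- small_random_model(seed = 5)
  model$betas$B <- model$betas$A  # identical classes, uniform priors
  set.seed(6)
  Y <- matrix(rpois(20, 10), 4, 5,
              dimnames = list(paste0("t", 1:4), model$gene_ids))
  X <- cbind(1, matrix(rnorm(8), 4, 2))
  dimnames(X) <- list(rownames(Y), model$feature_names)
  pred <- predict_radiogenomics_nb(model, count_matrix(t(Y)),
                                   covariate_matrix(X))
  expect_equal(pred$posterior_A, rep(0.5, 4), tolerance = 1e-12)
  expect_true(all(pred$predicted == "A"))
})

test_that("prior monotonicity: raising a class prior never lowers its posterior", {
  model <- small_random_model(seed = 9)
  set.seed(10)
  Y <- matrix(rpois(25, 12), 5, 5,
              dimnames = list(paste0("t", 1:5), model$gene_ids))
  X <- cbind(1, matrix(rnorm(10), 5, 2))
  dimnames(X) <- list(rownames(Y), model$feature_names)
  p_a <- seq(0.1, 0.9, by = 0.2)
  posts <- sapply(p_a, function(p) {
    m <- model
    m$priors <- c(A = p, B = 1 - p)
    predict_radiogenomics_nb(m, count_matrix(t(Y)),
                             covariate_matrix(X))$posterior_A
  })
  expect_true(all(apply(posts, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("fitting is deterministic and produces a structurally valid model", {
  p <- preset_scenarios()
  spec <- p$well_separated
  spec$n_per_class <- c(classA = 100L, classB = 100L)
  ds <- generate_dataset(spec, seed = 31)
  cfg <- training_config(k = 10, seed = 31)
  m1 <- fit_radiogenomics_nb(ds$counts, ds$covars, ds$labels, cfg)
  m2 <- fit_radiogenomics_nb(ds$counts, ds$covars, ds$labels, cfg)
  expect_identical(m1, m2)

  expect_length(m1$gene_ids, 10L)
  expect_identical(names(m1$betas), c("classA", "classB"))
  expect_identical(dim(m1$betas$classA), c(3L, 10L))
  expect_true(all(m1$dispersions > 0))
  expect_equal(unname(m1$priors), c(0.5, 0.5))  # uniform default
  expect_equal(sum(m1$priors), 1, tolerance = 1e-12)

  # empirical priors reflect training frequencies
  m3 <- fit_radiogenomics_nb(ds$counts, ds$covars, ds$labels,
                             training_config(k = 10, prior = "empirical"))
  expect_equal(unname(m3$priors), c(0.5, 0.5))

  # class with < 2 samples refuses to fit
  ids <- names(ds$labels)
  keep <- c(ids[ds$labels == "classA"], ids[ds$labels == "classB"][1])
  sub <- subset_ds(ds, keep)
  expect_error(fit_radiogenomics_nb(sub$counts, sub$covars, sub$labels, cfg),
               "fewer than 2")
})

test_that("label-permutation equivariance: renaming classes permutes parameters", {
  ds <- random_dataset(G = 20, n = 30, seed = 55)
  cfg <- training_config(k = 5, q = 0)
  m <- fit_radiogenomics_nb(ds$counts, ds$covars, ds$labels, cfg)
  # swap class names (and their declared order)
  swapped <- label_vector(ifelse(as.character(ds$labels) == "c1", "c2", "c1"),
                          names(ds$labels), class_set = c("c2", "c1"))
  m_sw <- fit_radiogenomics_nb(ds$counts, ds$covars, swapped, cfg)
  expect_identical(m$gene_ids, m_sw$gene_ids)
  expect_equal(m$betas$c1, m_sw$betas$c2, tolerance = 1e-12)
  expect_equal(m$betas$c2, m_sw$betas$c1, tolerance = 1e-12)
  expect_equal(m$dispersions, m_sw$dispersions, tolerance = 1e-12)

  te <- random_dataset(G = 20, n = 8, seed = 56)
  te_counts <- count_matrix(unclass(te$counts),
                            sample_ids = paste0("t", 1:8))
  te_cov <- covariate_matrix(unclass(te$covars),
                             sample_ids = paste0("t", 1:8))
  pr <- predict_radiogenomics_nb(m, te_counts, te_cov)
  pr_sw <- predict_radiogenomics_nb(m_sw, te_counts, te_cov)
  # class "c1" in the swapped model holds the samples originally labelled c2
  expect_equal(pr$posterior_c1, pr_sw$posterior_c2, tolerance = 1e-9)
  map <- c(c1 = "c2", c2 = "c1")
  expect_identical(unname(map[as.character(pr$predicted)]),
                   as.character(pr_sw$predicted))
})

test_that("prediction validates panel coverage and count guardrails", {
  model <- small_random_model(seed = 77)
  Y <- matrix(rpois(10, 9), 2, 5,
              dimnames = list(c("t1", "t2"), model$gene_ids))
  X <- cbind(1, matrix(0, 2, 2))
  dimnames(X) <- list(rownames(Y), model$feature_names)
  # missing gene
  expect_error(predict_radiogenomics_nb(
    model, count_matrix(t(Y)[-1, , drop = FALSE]), covariate_matrix(X)),
    "g1")
  # absurd count
  Y2 <- Y; Y2[1, 1] <- 2e9
  expect_error(predict_radiogenomics_nb(model, count_matrix(t(Y2)),
                                        covariate_matrix(X)),
               "guardrail")
  # covariate name mismatch
  Xbad <- X; colnames(Xbad) <- c("(Intercept)", "f1", "wrong")
  expect_error(predict_radiogenomics_nb(model, count_matrix(t(Y)),
                                        covariate_matrix(Xbad)),
               "covariate names")
})

test_that("NBLDA: equal class rates give uniform posteriors; matches a direct oracle", {
  # hand-built NBLDA model with identical rates in both classes
  genes <- paste0("g", 1:3)
  lam <- matrix(c(30, 50, 20, 30, 50, 20), 3, 2,
                dimnames = list(genes, c("A", "B")))
  model <- nbfusion:::new_nb_class_model(
    kind = "nblda", gene_ids = genes, class_set = c("A", "B"),
    feature_names = character(0),
    dispersions = setNames(c(0.2, 0.4, 0.3), genes),
    betas = NULL, lambda_rates = lam, priors = c(A = 0.5, B = 0.5),
    fit_metadata = list(mean_train_total = 100))
  set.seed(8)
  Y <- matrix(rpois(9, 25), 3, 3,
              dimnames = list(genes, paste0("t", 1:3)))
  pred <- predict_nblda(model, count_matrix(Y))
  expect_equal(pred$posterior_A, rep(0.5, 3), tolerance = 1e-12)

  # distinct rates: scores equal the direct per-gene pmf-product oracle
  model$lambda_rates[, "B"] <- c(10, 70, 20)
  pred2 <- predict_nblda(model, count_matrix(Y))
  for (i in 1:3) {
    s_t <- sum(Y[, i]) / 100
    for (cl in c("A", "B")) {
      manual <- sum(mapply(oracle_nb_log_pmf, Y[, i],
                           s_t * model$lambda_rates[, cl],
                           model$dispersions)) + log(0.5)
      expect_equal(pred2[[paste0("score_", cl)]][i], manual,
                   tolerance = 1e-10)
    }
  }

  # scale symmetry: with equal class total rates and near-Poisson dispersion
  # the score difference is sum_g y_g * log(rate ratio), so doubling all test
  # counts (and hence the implied s_t) cannot change the prediction
  model$lambda_rates[, "A"] <- c(30, 50, 20)
  model$lambda_rates[, "B"] <- c(50, 20, 30)   # same total 100
  model$dispersions[] <- 1e-6
  predA <- predict_nblda(model, count_matrix(Y))
  pred2x <- predict_nblda(model, count_matrix(2 * Y))
  expect_identical(as.character(predA$predicted),
                   as.character(pred2x$predicted))
})

test_that("NBLDA end-to-end on count-signal data beats chance", {
  p <- preset_scenarios()
  ds <- generate_dataset(p$count_only_signal, seed = 13)
  sp <- stratified_split(ds$labels, 0.8, seed = 13)
  tr <- subset_ds(ds, sp$train)
  te <- subset_ds(ds, sp$test)
  m <- fit_nblda(tr$counts, tr$labels, training_config(k = 10))
  acc <- mean(as.character(predict_nblda(m, te$counts)$predicted) ==
                as.character(te$labels))
  expect_gt(acc, 0.8)
})
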