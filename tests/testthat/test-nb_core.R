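test_that("nb_log_pmf: closed forms, Poisson limit, continuity and domain errors", {
  # y = 0 closed form: -(1/phi) * log(1 + phi*mu)
  expect_equal(nb_log_pmf(0, 2, 0.5), -2 * log(2), tolerance = 1e-12)
  for (mu in c(0.5, 5, 50)) {
    for (phi in c(0.05, 0.5, 2)) {
      expect_equal(nb_log_pmf(0, mu, phi), -log1p(phi * mu) / phi,
                   tolerance = 1e-12)
    }
  }

  # Poisson limit below the switch
  expect_equal(nb_log_pmf(3, 2, 1e-12), 3 * log(2) - 2 - log(6),
               tolerance = 1e-6)
  # continuity across the phi switch
  eps <- 1e-12
  expect_lt(abs(nb_log_pmf(7, 5, 1e-10 + eps) - nb_log_pmf(7, 5, 1e-10 - eps)),
            1e-6)

  # agrees with stats::dnbinom across a grid
  set.seed(1)
  for (i in 1:50) {
    y <- rpois(1, 30); mu <- runif(1, 0.1, 100); phi <- runif(1, 0.01, 3)
    expect_equal(nb_log_pmf(y, mu, phi), oracle_nb_log_pmf(y, mu, phi),
                 tolerance = 1e-10)
  }

  # no overflow for huge counts
  expect_true(is.finite(nb_log_pmf(1e9, 1e6, 0.7)))

  expect_error(nb_log_pmf(1, 0, 0.5), "mu")
  expect_error(nb_log_pmf(-1, 2, 0.5), "non-negative integer")
  expect_error(nb_log_pmf(1.5, 2, 0.5), "non-negative integer")
  expect_error(nb_log_pmf(1, 2, -0.1), "phi")
})

test_that("pmf sums to one over the support", {
  for (mu in c(1, 10, 50)) {
    for (phi in c(0.05, 0.5, 2)) {
      total <- sum(exp(nb_log_pmf(0:5000, mu, phi)))
      expect_gte(total, 1 - 1e-6)
      expect_lte(total, 1 + 1e-12)
    }
  }
})

test_that("sample_log_likelihood sums independent genes", {
  expect_equal(sample_log_likelihood(4, 3, 0.2), nb_log_pmf(4, 3, 0.2))
  y <- c(1, 0, 4); mu <- c(2, 1, 5); phi <- rep(0.5, 3)
  manual <- sum(mapply(oracle_nb_log_pmf, y, mu, phi))
  expect_equal(sample_log_likelihood(y, mu, phi), manual, tolerance = 1e-12)
  # permutation invariance
  p <- c(3, 1, 2)
  expect_equal(sample_log_likelihood(y[p], mu[p], phi[p]),
               sample_log_likelihood(y, mu, phi))
  expect_error(sample_log_likelihood(1:3, 1:2, 1:3), "lengths differ")
})

test_that("dispersion MLE matches a dense grid and is consistent in simulation", {
  # grid oracle on a 3-gene, 10-sample toy with pipeline class means
  set.seed(42)
  y <- matrix(rnbinom(30, size = 1 / 0.4, mu = 25), 3, 10)
  cm <- toy_counts(y, samples = sprintf("s%02d", 1:10))
  lv <- label_vector(rep(c("a", "b"), each = 5), colnames(cm))
  means <- compute_class_means(cm, lv)
  raw <- estimate_dispersion_raw(cm, means, lv)

  grid <- exp(seq(log(1e-6), log(1e3), length.out = 2000))
  step <- log(1e3 / 1e-6) / 1999
  for (g in 1:3) {
    mu_vec <- c(means$per_class$a$mu[g, ], means$per_class$b$mu[g, ])
    y_ord <- c(y[g, 1:5], y[g, 6:10])
    ll_grid <- vapply(grid, function(p)
      sum(oracle_nb_log_pmf(y_ord, mu_vec, p)), numeric(1))
    best <- grid[which.max(ll_grid)]
    expect_lt(abs(log(raw$phi_hat[g]) - log(best)), step + 1e-8)
    expect_gt(raw$tau_sq[g], 0)
  }

  # consistency: n = 2000, true phi = 0.5, means held at the true mu = 30
  hits <- 0L
  for (s in 1:100) {
    set.seed(5000 + s)
    yb <- rnbinom(2000, size = 1 / 0.5, mu = 30)
    cmb <- count_matrix(matrix(yb, 1, 2000,
                               dimnames = list("g1", sprintf("t%04d", 1:2000))))
    lvb <- label_vector(rep(c("a", "b"), 1000), colnames(cmb))
    mu_mat <- matrix(30, 1, 2000, dimnames = dimnames(cmb))
    rb <- estimate_dispersion_raw(cmb, make_class_means(mu_mat, lvb), lvb)
    if (abs(rb$phi_hat - 0.5) <= 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  # Poisson data drives the estimate to the lower clip bound
  lower_hits <- 0L
  for (s in 1:20) {
    set.seed(6000 + s)
    yp <- rpois(500, 25)
    cmp <- count_matrix(matrix(yp, 1, 500,
                               dimnames = list("g1", sprintf("t%03d", 1:500))))
    lvp <- label_vector(rep(c("a", "b"), 250), colnames(cmp))
    mu_mat <- matrix(25, 1, 500, dimnames = dimnames(cmp))
    rp <- estimate_dispersion_raw(cmp, make_class_means(mu_mat, lvp), lvp)
    if (rp$phi_hat <= 1e-3) lower_hits <- lower_hits + 1L
  }
  expect_gt(lower_hits, 10L)
})

test_that("weighted-likelihood shrinkage reproduces the hand-worked example", {
  raw <- data.frame(gene_id = c("g1", "g2"), phi_hat = c(0.2, 0.6),
                    tau_sq = c(0.01, 0.01))
  # independent arithmetic with tau0^2 fixed at 0.03:
  # alpha = 1 / ((0.03/0.01) * 2) = 1/6; phi0 = 0.4
  # phi1_WL = (0.2/0.01 + (1/6)(0.2/0.01 + 0.6/0.01)) /
  #           (1/0.01  + (1/6)(2/0.01))
  sh <- shrink_dispersion_wl(raw, tau0_sq = 0.03)
  expect_equal(sh$alpha, 1 / 6, tolerance = 1e-12)
  expect_equal(sh$phi0, 0.4, tolerance = 1e-12)
  expect_equal(sh$phi_wl[1],
               (0.2 / 0.01 + (1 / 6) * (0.2 / 0.01 + 0.6 / 0.01)) /
                 (1 / 0.01 + (1 / 6) * (2 / 0.01)),
               tolerance = 1e-12)

  # alpha = 0 leaves the raw estimates untouched
  sh0 <- shrink_dispersion_wl(raw, alpha = 0)
  expect_equal(sh0$phi_wl, raw$phi_hat, tolerance = 1e-15)

  # all-equal estimates are a fixed point
  raw_eq <- data.frame(gene_id = paste0("g", 1:4), phi_hat = rep(0.37, 4),
                       tau_sq = c(0.01, 0.02, 0.03, 0.04))
  sh_eq <- shrink_dispersion_wl(raw_eq)
  expect_equal(sh_eq$phi_wl, rep(0.37, 4), tolerance = 1e-12)
  expect_equal(sh_eq$phi0, 0.37, tolerance = 1e-12)

  # contraction: the shrunken value always lies between raw and phi0
  set.seed(9)
  for (i in 1:20) {
    rw <- data.frame(gene_id = paste0("g", 1:15),
                     phi_hat = runif(15, 0.05, 2),
                     tau_sq = runif(15, 1e-4, 0.1))
    s <- shrink_dispersion_wl(rw)
    expect_true(all(abs(s$phi_wl - s$phi0) <= abs(s$phi_hat - s$phi0) + 1e-12))
  }

  # single gene: warning, unshrunken
  expect_warning(s1 <- shrink_dispersion_wl(
    data.frame(gene_id = "g1", phi_hat = 0.5, tau_sq = 0.01)), "single gene")
  expect_equal(s1$phi_wl, 0.5)
})

test_that("fit_beta solves the log-linear system, incl. rank deficiency", {
  # intercept-only design: beta = mean of log means
  X <- covariate_matrix(matrix(1, 2, 1, dimnames = list(c("s1", "s2"),
                                                        "(Intercept)")))
  mu <- matrix(c(exp(2), exp(4)), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(fit_beta(X, mu)$betas[1, 1]), 3, tolerance = 1e-12)

  # exactly linear log-means are interpolated
  set.seed(3)
  Xm <- cbind(1, matrix(rnorm(20), 10, 2))
  colnames(Xm) <- c("(Intercept)", "f1", "f2")
  rownames(Xm) <- sprintf("s%02d", 1:10)
  B_true <- matrix(c(2, 0.5, -0.3, 1, -0.2, 0.7), 3, 2)
  mu_lin <- t(exp(Xm %*% B_true))
  rownames(mu_lin) <- c("g1", "g2")
  fb <- fit_beta(covariate_matrix(Xm), mu_lin)
  expect_equal(unname(fb$betas), unname(B_true), tolerance = 1e-10)
  expect_true(all(fb$rms_residual < 1e-10))

  # duplicated covariate column: minimum-norm solution matches the ridge
  # limit (ridge 1e-8: small enough to sit in the limit, large enough that
  # the normal equations are still numerically meaningful in doubles)
  Xd <- cbind(Xm, f2b = Xm[, "f2"])
  mu_one <- mu_lin[1, , drop = FALSE]
  fbd <- fit_beta(covariate_matrix(Xd), mu_one)
  ridge <- solve(crossprod(Xd) + 1e-8 * diag(4), crossprod(Xd, log(mu_one[1, ])))
  expect_equal(unname(fbd$betas[, 1]), unname(ridge[, 1]), tolerance = 1e-6)

  expect_error(fit_beta(covariate_matrix(Xm), -mu_lin), "positive")
})

test_that("simulated NB counts satisfy the variance identity", {
  set.seed(77)
  mu <- 20; phi <- 0.5; n <- 1e5
  lam <- rgamma(n, shape = 1 / phi, scale = phi * mu)
  y <- rpois(n, lam)
  expect_lt(abs(mean(y) - mu) / mu, 0.02)
  expect_lt(abs(var(y) - (mu + phi * mu^2)) / (mu + phi * mu^2), 0.05)
})
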