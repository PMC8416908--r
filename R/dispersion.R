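## Gene-wise dispersion: profile MLE with class means held fixed, then
## weighted-likelihood empirical-Bayes shrinkage toward a common value.

.PHI_MIN <- 1e-6
.PHI_MAX <- 1e3
.TAU_FLOOR <- 1e-8
.TAU_UNINFORMATIVE <- 1e6  # boundary fits carry essentially no curvature info

#' Raw per-gene dispersion estimates with curvature-based uncertainties
#'
#' For each gene the dispersion maximizes the NB log-likelihood over all
#' training samples with the means fixed at the class-wise fitted values
#' `mu_igc`, by bounded scalar optimization of `log(phi)` over
#' `[log(1e-6), log(1e3)]`.  The uncertainty `tau_g^2` is the inverse of the
#' numerically differentiated negative second derivative of that
#' log-likelihood at the optimum (observed Fisher information), floored at
#' `1e-8`; non-concave curvature (boundary solutions) yields an essentially
#' uninformative `tau_g^2 = 1e6`.
#'
#' @param counts a [count_matrix()] on the panel genes.
#' @param class_means a `class_means` from [compute_class_means()] on the same
#'   genes and samples.
#' @param labels the [label_vector()] used to build `class_means`.
#' @return data.frame with columns `gene_id`, `phi_hat`, `tau_sq`.
#' @export
estimate_dispersion_raw <- function(counts, class_means, labels) {
  m <- unclass(counts)
  labels <- labels[colnames(counts)]
  if (!identical(rownames(m), class_means$gene_ids)) {
    stop("estimate_dispersion_raw: genes do not match class_means", call. = FALSE)
  }
  G <- nrow(m)
  # per-sample means per gene, classes interleaved back into sample order
  mu_mat <- matrix(NA_real_, G, ncol(m), dimnames = dimnames(m))
  for (cl in class_means$class_set) {
    sel <- which(labels == cl)
    mu_mat[, sel] <- class_means$per_class[[cl]]$mu[, colnames(m)[sel], drop = FALSE]
  }
  phi_hat <- numeric(G)
  tau_sq <- numeric(G)
  for (g in seq_len(G)) {
    y <- m[g, ]
    mu <- mu_mat[g, ]
    nll <- function(lphi) -sum(nb_log_pmf(y, mu, exp(lphi)))
    res <- tryCatch(
      stats::optimize(nll, lower = log(.PHI_MIN), upper = log(.PHI_MAX),
                      tol = 1e-8),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) {
      phi_hat[g] <- .PHI_MIN
      tau_sq[g] <- .TAU_UNINFORMATIVE
      message(sprintf("estimate_dispersion_raw: non-finite likelihood for gene '%s'; falling back to phi_min",
                      rownames(m)[g]))
      next
    }
    phi <- exp(res$minimum)
    phi_hat[g] <- min(max(phi, .PHI_MIN), .PHI_MAX)
    # observed information in phi by central difference of the log-likelihood
    h <- max(1e-4 * phi, 1e-7)
    ll <- function(p) sum(nb_log_pmf(y, mu, max(p, 0)))
    d2 <- (ll(phi + h) - 2 * ll(phi) + ll(phi - h)) / h^2
    info <- -d2
    tau_sq[g] <- if (is.finite(info) && info > 0) {
      max(1 / info, .TAU_FLOOR)
    } else {
      .TAU_UNINFORMATIVE
    }
  }
  data.frame(gene_id = rownames(m), phi_hat = phi_hat, tau_sq = tau_sq,
             stringsAsFactors = FALSE)
}

#' Weighted-likelihood empirical-Bayes shrinkage of dispersions
#'
#' Hierarchical normal model for the raw estimates: `phi_hat_g | phi_g ~
#' N(phi_g, tau_g^2)` and `phi_g ~ N(phi0, tau0^2)`.  The common value `phi0`
#' is the precision-weighted mean of the raw estimates; the prior variance
#' `tau0^2` is the method-of-moments value `max(var(phi_hat) - mean(tau^2),
#' 1e-8)`; the common-likelihood weight is `alpha = 1 / sum(tau0^2 / tau_g^2)`.
#' The shrunken estimate
#' \deqn{\hat\phi_g^{WL} = \frac{\hat\phi_g/\tau_g^2 +
#'   \alpha\sum_i \hat\phi_i/\tau_i^2}{1/\tau_g^2 + \alpha\sum_i 1/\tau_i^2}}
#' lies between the raw estimate and `phi0`; results are clipped to
#' `[1e-6, 1e3]`.
#'
#' @param raw data.frame from [estimate_dispersion_raw()] (columns `gene_id`,
#'   `phi_hat`, `tau_sq`).
#' @param alpha optional override of the common-likelihood weight (e.g. 0 to
#'   disable shrinkage).
#' @param tau0_sq optional override of the prior variance.
#' @return A `dispersion_estimates` list: `gene_id`, `phi_hat`, `tau_sq`,
#'   `phi_wl`, `phi0`, `tau0_sq`, `alpha`.
#' @export
shrink_dispersion_wl <- function(raw, alpha = NULL, tau0_sq = NULL) {
  phi <- raw$phi_hat
  tau2 <- raw$tau_sq
  G <- length(phi)
  if (G < 1L) stop("shrink_dispersion_wl: no genes", call. = FALSE)
  if (G == 1L) {
    warning("shrink_dispersion_wl: single gene; returning the raw estimate unshrunken")
    return(structure(list(gene_id = raw$gene_id, phi_hat = phi, tau_sq = tau2,
                          phi_wl = phi, phi0 = phi, tau0_sq = NA_real_,
                          alpha = 0), class = "dispersion_estimates"))
  }
  w <- 1 / tau2
  phi0 <- sum(phi * w) / sum(w)
  if (is.null(tau0_sq)) {
    tau0_sq <- max(stats::var(phi) - mean(tau2), .TAU_FLOOR)
  }
  if (is.null(alpha)) {
    alpha <- 1 / sum(tau0_sq / tau2)
  }
  sw_phi <- sum(phi * w)
  sw <- sum(w)
  phi_wl <- (phi * w + alpha * sw_phi) / (w + alpha * sw)
  phi_wl <- pmin(pmax(phi_wl, .PHI_MIN), .PHI_MAX)
  structure(list(gene_id = raw$gene_id, phi_hat = phi, tau_sq = tau2,
                 phi_wl = phi_wl, phi0 = phi0, tau0_sq = tau0_sq,
                 alpha = alpha),
            class = "dispersion_estimates")
}
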