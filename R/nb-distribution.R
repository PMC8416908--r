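## Negative Binomial probability kernel.
## Parameterization: E(Y) = mu, Var(Y) = mu + phi * mu^2; phi -> 0 is Poisson.
## All arithmetic in log space via lgamma; safe for counts up to 1e9.

.PHI_POISSON_SWITCH <- 1e-10

#' Negative Binomial log-pmf (mean/dispersion parameterization)
#'
#' \deqn{P(Y=y) = \frac{\Gamma(\phi^{-1}+y)}{\Gamma(\phi^{-1})\,y!}
#'   \left(\frac{\phi\mu}{1+\phi\mu}\right)^{y}
#'   \left(\frac{1}{1+\phi\mu}\right)^{1/\phi}}
#'
#' For `phi` below `1e-10` the Poisson log-pmf limit is returned, keeping the
#' function continuous across the switch.  Vectorized with the usual recycling.
#'
#' @param y non-negative integer count(s).
#' @param mu positive mean(s).
#' @param phi non-negative dispersion(s); `Var(Y) = mu + phi*mu^2`.
#' @return log-probability, same length as the recycled arguments.
#' @export
nb_log_pmf <- function(y, mu, phi) {
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(as.numeric(y), n)
  mu <- rep_len(as.numeric(mu), n)
  phi <- rep_len(as.numeric(phi), n)
  if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
    stop("nb_log_pmf: y must be non-negative integer(s)", call. = FALSE)
  }
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("nb_log_pmf: mu must be positive", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi < 0)) {
    stop("nb_log_pmf: phi must be non-negative", call. = FALSE)
  }
  out <- numeric(n)
  pois <- phi < .PHI_POISSON_SWITCH
  if (any(pois)) {
    out[pois] <- y[pois] * log(mu[pois]) - mu[pois] - lgamma(y[pois] + 1)
  }
  if (any(!pois)) {
    yk <- y[!pois]; mk <- mu[!pois]; pk <- phi[!pois]
    inv <- 1 / pk
    l1p <- log1p(pk * mk)
    # lgamma(1/phi + y) - lgamma(1/phi) + y*log(phi) cancels catastrophically
    # for tiny phi (1/phi ~ 1e10); use sum_{j=0}^{y-1} log(1 + j*phi) there
    gterm <- numeric(length(yk))
    small <- pk < 1e-8 & yk < 1e6
    if (any(small)) {
      gterm[small] <- mapply(function(yy, pp) {
        if (yy == 0) 0 else sum(log1p(pp * seq_len(yy - 1)))
      }, yk[small], pk[small])
      gterm[small] <- gterm[small] + yk[small] * log(mk[small])
    }
    if (any(!small)) {
      gterm[!small] <- lgamma(inv[!small] + yk[!small]) - lgamma(inv[!small]) +
        yk[!small] * (log(pk[!small]) + log(mk[!small]))
    }
    out[!pois] <- gterm - lgamma(yk + 1) - yk * l1p - inv * l1p
  }
  out
}

#' Joint log-likelihood of one sample across independent genes
#'
#' Genes are modelled as independent, so the sample log-likelihood is the sum
#' of per-gene NB log-pmfs.
#'
#' @param y_vec per-gene counts.
#' @param mu_vec per-gene means (positive).
#' @param phi_vec per-gene dispersions (non-negative).
#' @return scalar log-likelihood.
#' @export
sample_log_likelihood <- function(y_vec, mu_vec, phi_vec) {
  if (length(y_vec) != length(mu_vec) || length(y_vec) != length(phi_vec)) {
    stop("sample_log_likelihood: y_vec, mu_vec, phi_vec lengths differ",
         call. = FALSE)
  }
  sum(nb_log_pmf(y_vec, mu_vec, phi_vec))
}
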