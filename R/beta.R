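## Log-linear link between covariates and NB means: per-gene, per-class least
## squares of log(mu_igc) on X, minimum-norm under rank deficiency.

# Moore-Penrose pseudoinverse via SVD
.pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' Estimate regression coefficients linking covariates to log NB means
#'
#' Solves, for each gene `g`, the least-squares problem
#' `log(mu_igc) = X_i beta_gc` over the class-`c` training samples.  The
#' solution uses the SVD pseudoinverse, so rank-deficient designs yield the
#' minimum-norm solution.  With an intercept-only design this reduces to the
#' mean of the log means.
#'
#' @param covars a [covariate_matrix()] restricted to the class-`c` samples
#'   (rows), including the intercept column if one is used.
#' @param mu genes x samples matrix of positive fitted means `mu_igc` for the
#'   same samples (column order must match the covariate rows).
#' @return list with `betas` (p x G matrix, one coefficient vector per gene)
#'   and `rms_residual` (per-gene root-mean-square residual of the log fit).
#' @export
fit_beta <- function(covars, mu) {
  X <- unclass(covars)
  if (ncol(mu) != nrow(X)) {
    stop("fit_beta: number of samples in mu and covars differ", call. = FALSE)
  }
  if (any(mu <= 0)) {
    stop("fit_beta: all means must be positive (apply the pseudo-total rule first)",
         call. = FALSE)
  }
  L <- t(log(mu))                      # n_c x G response matrix
  B <- .pinv(X) %*% L                  # p x G coefficients
  fitted <- X %*% B
  rms <- sqrt(colMeans((L - fitted)^2))
  dimnames(B) <- list(colnames(X), rownames(mu))
  list(betas = B, rms_residual = stats::setNames(rms, rownames(mu)))
}
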