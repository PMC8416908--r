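## Low-count quantile filtering, NB likelihood-ratio gene ranking and class-wise
## size-factor / mean computation.

#' Filter out low-abundance genes by a quantile of per-gene mean counts
#'
#' Keeps exactly the genes whose mean count across all samples is strictly
#' greater than the `q`-quantile (linear-interpolation type 7) of all genes'
#' means.  Gene order is preserved.
#'
#' @param counts a [count_matrix()].
#' @param q quantile threshold in \code{[0, 1]}; default 0.25.
#' @return filtered [count_matrix()].
#' @export
quantile_filter <- function(counts, q = 0.25) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1) {
    stop("quantile_filter: q must be a single value in [0, 1]", call. = FALSE)
  }
  gene_means <- rowMeans(counts)
  thr <- stats::quantile(gene_means, probs = q, names = FALSE, type = 7)
  keep <- gene_means > thr
  if (!any(keep)) {
    stop(sprintf("quantile_filter: no gene has mean count strictly above the q=%g quantile (%.4g)",
                 q, thr), call. = FALSE)
  }
  count_matrix(unclass(counts)[keep, , drop = FALSE])
}

# method-of-moments dispersion from overall sample moments, floored at 0
.mom_dispersion <- function(y) {
  m <- mean(y)
  if (m <= 0) return(0)
  v <- stats::var(y)
  min(max((v - m) / m^2, 0), 1e3)
}

#' Rank genes by a per-gene Negative Binomial likelihood-ratio statistic
#'
#' In-repo stand-in for external differential-expression tooling: per gene, a
#' likelihood-ratio statistic
#' \eqn{2[\ell(\text{class-specific means}) - \ell(\text{pooled mean})]}
#' with a shared method-of-moments dispersion per gene.  For fixed dispersion
#' the NB mean MLE is the sample mean, so both likelihoods are evaluated at
#' sample means.  Genes are sorted by statistic descending, ties broken by
#' gene id.
#'
#' @param counts a filtered [count_matrix()].
#' @param labels a [label_vector()] with exactly 2 classes present.
#' @return A `gene_ranking` data.frame with columns `gene_id`, `statistic`,
#'   `direction` (sign of class-2 minus class-1 mean), sorted by statistic.
#' @export
rank_genes_lrt <- function(counts, labels) {
  labels <- labels[colnames(counts)]
  if (anyNA(labels)) {
    stop("rank_genes_lrt: labels missing for some samples", call. = FALSE)
  }
  if (nlevels(labels) != 2L) {
    stop("rank_genes_lrt: ranking requires exactly 2 classes", call. = FALSE)
  }
  .require_all_classes(labels, 1L)
  cls <- levels(labels)
  idx1 <- which(labels == cls[1L])
  idx2 <- which(labels == cls[2L])
  m <- unclass(counts)
  stat <- numeric(nrow(m))
  dir <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    y <- m[g, ]
    phi <- .mom_dispersion(y)
    mu0 <- max(mean(y), 0.5 / length(y))
    y1 <- y[idx1]; y2 <- y[idx2]
    mu1 <- max(mean(y1), 0.5 / length(y1))
    mu2 <- max(mean(y2), 0.5 / length(y2))
    ll_alt <- sum(nb_log_pmf(y1, mu1, phi)) + sum(nb_log_pmf(y2, mu2, phi))
    ll_null <- sum(nb_log_pmf(y, mu0, phi))
    stat[g] <- max(2 * (ll_alt - ll_null), 0)
    dir[g] <- sign(mu2 - mu1)
  }
  ord <- order(-stat, rownames(m))
  structure(
    data.frame(gene_id = rownames(m)[ord], statistic = stat[ord],
               direction = dir[ord], stringsAsFactors = FALSE),
    class = c("gene_ranking", "data.frame")
  )
}

#' Take the top-k genes of a ranking
#'
#' Accepts either a `gene_ranking` from [rank_genes_lrt()] or any externally
#' supplied character vector of gene ids (so users can inject their own
#' differential-expression results).
#'
#' @param ranking a `gene_ranking` or character vector of gene ids.
#' @param k panel size; must not exceed the number of ranked genes.
#' @return character vector of `k` gene ids in ranking order.
#' @export
top_k_panel <- function(ranking, k) {
  ids <- if (is.character(ranking)) ranking else ranking$gene_id
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("top_k_panel: k must be a positive integer", call. = FALSE)
  }
  if (k > length(ids)) {
    stop(sprintf("top_k_panel: k=%d exceeds the %d available genes",
                 k, length(ids)), call. = FALSE)
  }
  ids[seq_len(k)]
}

#' Class-wise size factors, per-gene totals and fitted means
#'
#' Size factor of sample `i` in class `c`: its total read count divided by the
#' class grand total, so size factors sum to exactly 1 within each class.
#' Per-gene class total `lambda_gc` is the column sum over class samples; a
#' zero total is replaced by the pseudo-total 0.5 so downstream logs stay
#' finite.  The fitted mean is `mu_igc = s_ic * lambda_gc`.
#'
#' @param counts a [count_matrix()] (typically restricted to a gene panel).
#' @param labels a [label_vector()]; every class must be non-empty.
#' @return A `class_means` list with per-class components `size_factors`
#'   (named per sample), `lambda` (named per gene) and `mu` (genes x samples
#'   matrix), plus `class_set` and `gene_ids`.
#' @export
compute_class_means <- function(counts, labels) {
  labels <- labels[colnames(counts)]
  if (anyNA(labels)) {
    stop("compute_class_means: labels missing for some samples", call. = FALSE)
  }
  .require_all_classes(labels, 1L)
  m <- unclass(counts)
  cls <- levels(labels)
  per_class <- lapply(cls, function(cl) {
    sub <- m[, labels == cl, drop = FALSE]
    grand <- sum(sub)
    if (grand <= 0) {
      stop(sprintf("compute_class_means: class '%s' has zero total counts", cl),
           call. = FALSE)
    }
    s <- colSums(sub) / grand
    lambda <- rowSums(sub)
    lambda[lambda == 0] <- 0.5  # pseudo-total keeps log(mu) finite
    mu <- outer(lambda, s)
    list(size_factors = s, lambda = lambda, mu = mu)
  })
  names(per_class) <- cls
  structure(list(per_class = per_class, class_set = cls,
                 gene_ids = rownames(m)),
            class = "class_means")
}
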