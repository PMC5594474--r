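#' Cap the decomposition order by the number of samples
#'
#' When the requested number of components exceeds what the sample size can
#' support, the order is reduced to 0.9 times the number of samples (moderate
#' dimension reduction improves fastICA convergence), never below 2.
#'
#' @param M_requested Requested number of components.
#' @param n_samples Number of samples in the dataset.
#' @return The capped order: `min(M_requested, floor(0.9 * n_samples))`,
#'   at least 2.
#' @export
cap_order <- function(M_requested, n_samples) {
  stopifnot(n_samples >= 3)
  max(2L, min(as.integer(M_requested), as.integer(floor(0.9 * n_samples))))
}

#' PCA reduction and whitening of an expression matrix
#'
#' The matrix is double-centered (gene means across samples and sample means
#' across genes removed), the sample-space covariance computed across genes is
#' eigendecomposed, and the top `M` principal directions are rescaled to unit
#' variance. Rows of the whitened matrix `Z` (M x genes) then have zero mean,
#' unit variance and zero mutual correlation over genes — the standard fastICA
#' preprocessing. Because the centered matrix has rank at most
#' `min(genes, samples - 1)`, `M` may not exceed that bound.
#'
#' @param X An [expression_matrix()] (genes x samples).
#' @param M Number of retained dimensions, `2 <= M <= min(genes, samples - 1)`.
#' @return A `whitened_data` list: `Z` (M x genes whitened data), `basis`
#'   (samples x M eigenvectors), `sdev` (singular standard deviations of the
#'   retained components), `eigenvalues` (full spectrum),
#'   `explained_variance_fraction` (cumulative variance of the top `M`),
#'   `centered` (the double-centered genes x samples matrix), plus ids.
#' @export
whiten_reduce <- function(X, M) {
  v <- as_expression_values(X)
  n_g <- nrow(v)
  p <- ncol(v)
  M <- as.integer(M)
  if (M < 2L || M > min(n_g, p - 1L)) {
    stop(sprintf("M = %d out of range [2, %d]", M, min(n_g, p - 1L)),
         call. = FALSE)
  }
  # double centering: remove per-gene baseline and per-sample offset
  vc <- v - rowMeans(v)
  vc <- sweep(vc, 2L, colMeans(vc))
  C <- crossprod(vc) / (n_g - 1)          # samples x samples
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  if (lambda[M] <= max(lambda) * 1e-12) {
    stop(sprintf("M = %d exceeds the numerical rank of the centered matrix", M),
         call. = FALSE)
  }
  E <- eig$vectors[, seq_len(M), drop = FALSE]
  scores <- vc %*% E                       # genes x M, col variance lambda_j
  Z <- t(sweep(scores, 2L, sqrt(lambda[seq_len(M)]), "/"))
  dimnames(Z) <- list(NULL, rownames(v))
  structure(list(
    Z = Z,
    basis = E,
    sdev = sqrt(lambda[seq_len(M)]),
    eigenvalues = lambda,
    explained_variance_fraction = sum(lambda[seq_len(M)]) / sum(lambda),
    centered = vc,
    gene_ids = rownames(v),
    sample_ids = colnames(v),
    M = M
  ), class = "whitened_data")
}
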