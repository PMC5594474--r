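#' Pearson correlations between pooled components
#'
#' Correlation matrix between the gene-space weight vectors of all K*M pooled
#' components. Constant (zero-variance) component vectors make the correlation
#' undefined and abort with the offending run/component named.
#'
#' @param raw A `raw_component_set` from [run_multi_ica()].
#' @return Symmetric (K*M) x (K*M) correlation matrix.
#' @export
component_correlations <- function(raw) {
  comps <- raw$components
  sds <- apply(comps, 1L, stats::sd)
  if (any(sds == 0)) {
    i <- which(sds == 0)[1]
    stop(sprintf("component %d of run %d is constant; correlation undefined",
                 (i - 1L) %% raw$order + 1L, raw$run_index[i]), call. = FALSE)
  }
  R <- stats::cor(t(comps))
  R[R > 1] <- 1
  R[R < -1] <- -1
  R
}

#' Cluster pooled components across runs
#'
#' Agglomerative hierarchical clustering of the K*M pooled components with
#' dissimilarity `1 - |r_ij|` on gene-space weight vectors, cut to exactly
#' `M` clusters.
#'
#' @param raw A `raw_component_set`.
#' @param control An [ica_control()]; `control$linkage` selects the
#'   agglomeration method (default average).
#' @param corr Optional precomputed correlation matrix (from
#'   [component_correlations()]).
#' @return A `component_clustering`: `assignments` (cluster label per pooled
#'   component), `clusters` (list of member index vectors), `corr`.
#' @export
cluster_components <- function(raw, control = ica_control(), corr = NULL) {
  if (is.null(corr)) corr <- component_correlations(raw)
  M <- raw$order
  if (M == 1L) {
    assignments <- rep(1L, nrow(corr))
  } else {
    d <- stats::as.dist(1 - abs(corr))
    hc <- stats::hclust(d, method = control$linkage)
    assignments <- stats::cutree(hc, k = M)
  }
  structure(list(
    assignments = assignments,
    clusters = split(seq_along(assignments), assignments),
    corr = corr,
    order = M
  ), class = "component_clustering")
}

#' Stability index of component clusters
#'
#' The icasso cluster-quality index: average within-cluster absolute
#' correlation minus average between-cluster absolute correlation,
#' \deqn{I_q(C_k) = \frac{1}{|C_k|^2}\sum_{i,j \in C_k} |r_{ij}|
#'   - \frac{1}{|C_k| \sum_{l \ne k} |C_l|}
#'     \sum_{i \in C_k}\sum_{j \notin C_k} |r_{ij}|.}
#' `I_q = 1` corresponds to perfect clustering: all members mutually
#' correlated with `|r| = 1` and orthogonal to every other component. For a
#' single-cluster partition the between-cluster term (whose denominator
#' vanishes) is defined as 0.
#'
#' @param clustering A `component_clustering` from [cluster_components()],
#'   or a list of member index vectors.
#' @param corr Correlation matrix covering all members (defaults to the one
#'   stored in `clustering`).
#' @return Numeric vector of `I_q` values, one per cluster, in cluster order.
#' @export
stability_index <- function(clustering, corr = NULL) {
  if (inherits(clustering, "component_clustering")) {
    clusters <- clustering$clusters
    if (is.null(corr)) corr <- clustering$corr
  } else {
    clusters <- clustering
  }
  if (is.null(corr)) stop("a correlation matrix is required", call. = FALSE)
  if (any(lengths(clusters) == 0L)) stop("empty cluster", call. = FALSE)
  n <- nrow(corr)
  a <- abs(corr)
  vapply(clusters, function(Ck) {
    sz <- length(Ck)
    intra <- sum(a[Ck, Ck]) / sz^2
    n_out <- n - sz
    inter <- if (n_out == 0L) 0 else sum(a[Ck, -Ck, drop = FALSE]) / (sz * n_out)
    intra - inter
  }, numeric(1))
}

#' Average stability of the top-ranked components
#'
#' `S_M(k)`: the mean stability index of the `k` most stable clusters;
#' `k = "all"` gives the overall average `S(M)` of the profile.
#'
#' @param stabilities Stability indices sorted non-increasing.
#' @param k Number of top components to average, or `"all"`.
#' @return A single number.
#' @export
average_stability <- function(stabilities, k = "all") {
  if (identical(k, "all")) return(mean(stabilities))
  k <- as.integer(k)
  if (k < 1L || k > length(stabilities)) {
    stop("k must be in [1, ", length(stabilities), "]", call. = FALSE)
  }
  mean(stabilities[seq_len(k)])
}

#' Extract cluster representatives (centrotypes)
#'
#' For each cluster the centrotype is the member maximizing the sum of
#' absolute correlations to its cluster co-members (ties broken towards the
#' lowest member index). With `control$centrotype = "mean"` a sign-aligned
#' average of the members is used instead.
#'
#' @param clustering A `component_clustering`.
#' @param raw The `raw_component_set` that was clustered.
#' @param control An [ica_control()].
#' @return List with `metagenes` (M x genes, unit-norm rows, in cluster
#'   order), `centrotype_index` (pooled row index per cluster; `NA` for mean
#'   representatives) and `scores` (per-cluster centrotype scores).
#' @export
extract_centrotypes <- function(clustering, raw, control = ica_control()) {
  a <- abs(clustering$corr)
  comps <- raw$components
  idx <- integer(length(clustering$clusters))
  mg <- matrix(NA_real_, length(clustering$clusters), ncol(comps))
  colnames(mg) <- colnames(comps)
  scores <- numeric(length(idx))
  for (k in seq_along(clustering$clusters)) {
    Ck <- clustering$clusters[[k]]
    s <- rowSums(a[Ck, Ck, drop = FALSE])
    best <- which.max(s)                 # ties -> lowest index
    scores[k] <- s[best]
    if (control$centrotype == "member") {
      idx[k] <- Ck[best]
      mg[k, ] <- comps[Ck[best], ]
    } else {
      ref <- comps[Ck[best], ]
      signs <- sign(comps[Ck, , drop = FALSE] %*% ref)
      signs[signs == 0] <- 1
      m <- colMeans(comps[Ck, , drop = FALSE] * as.numeric(signs))
      mg[k, ] <- m / sqrt(sum(m^2))
      idx[k] <- NA_integer_
    }
  }
  list(metagenes = mg, centrotype_index = idx, scores = scores)
}

#' Orient a component so its heaviest tail is positive
#'
#' The weight vector is standardized to zero mean and unit variance; the
#' weight of each tail is the total absolute sum of standardized weights
#' beyond +/- `tail_sd`. If the negative tail is heavier the sign is flipped.
#' When both tails are empty or exactly tied, the sign of the skewness
#' decides; zero skewness leaves the vector unchanged. Idempotent.
#'
#' @param weights Non-constant numeric gene-weight vector (names preserved).
#' @param tail_sd Tail threshold in standard deviations (default 3).
#' @return The standardized, oriented vector.
#' @export
orient_component <- function(weights, tail_sd = 3) {
  s <- stats::sd(weights)
  if (!is.finite(s) || s == 0) stop("constant weight vector", call. = FALSE)
  z <- (weights - mean(weights)) / s
  pos <- sum(z[z > tail_sd])
  neg <- sum(-z[z < -tail_sd])
  flip <- if (pos != neg) {
    neg > pos
  } else {
    skew <- mean(z^3)
    skew < 0
  }
  if (flip) -z else z
}

#' Stabilized ICA decomposition at a fixed order
#'
#' The full per-M protocol: PCA reduction and whitening, `K` fastICA runs
#' from random starts, clustering of the pooled components with dissimilarity
#' `1 - |r|`, the icasso stability index per cluster, extraction of cluster
#' centrotypes as the final metagenes, orientation of each metagene so its
#' heaviest tail is positive, and re-estimation of the mixing matrix by least
#' squares. Components are returned ranked by decreasing stability.
#'
#' @inheritParams run_multi_ica
#' @param keep_raw Keep the pooled per-run components in the result
#'   (default `FALSE`; they are large).
#' @return An `ica_decomposition`: `metagenes` (M x genes, standardized and
#'   oriented rows named `IC1..ICM`), `mixing` (samples x M), `stabilities`
#'   (non-increasing), `order`, `runs`, `seed`,
#'   `explained_variance_fraction`, `component_stats` (tibble with rank,
#'   stability, kurtosis and per-component explained variance share),
#'   `run_log`, and optionally `raw`.
#' @export
decompose_stabilized <- function(X, M, K = 100L, seed = 1L,
                                 control = ica_control(), keep_raw = FALSE) {
  wh <- if (inherits(X, "whitened_data")) X else {
    M_cap <- cap_order(M, length_samples(X))
    if (M_cap < M) {
      warning("order capped from ", M, " to ", M_cap,
              " (0.9 x number of samples)", call. = FALSE)
      M <- M_cap
    }
    whiten_reduce(X, M)
  }
  M <- wh$M
  raw <- run_multi_ica(wh, M, K = K, seed = seed, control = control)
  clustering <- cluster_components(raw, control = control)
  iq <- stability_index(clustering)
  cent <- extract_centrotypes(clustering, raw, control = control)
  ord <- order(iq, decreasing = TRUE)
  iq <- unname(iq[ord])
  mg <- cent$metagenes[ord, , drop = FALSE]
  mg <- t(apply(mg, 1L, orient_component, tail_sd = control$orientation_sd))
  colnames(mg) <- wh$gene_ids
  rownames(mg) <- paste0("IC", seq_len(M))
  # mixing by least squares: t(centered) ~ A %*% mg
  G <- tcrossprod(mg)                      # M x M gram
  A <- t(wh$centered) %*% t(mg) %*% solve(G)
  dimnames(A) <- list(wh$sample_ids, rownames(mg))
  total_ss <- sum(wh$centered^2)
  comp_var <- colSums(A^2) * rowSums(mg^2) / total_ss
  kurt <- apply(mg, 1L, function(w) mean(w^4) - 3)
  stats_tbl <- tibble::tibble(
    component = rownames(mg),
    rank = seq_len(M),
    stability = iq,
    kurtosis = kurt,
    variance_share = comp_var
  )
  structure(list(
    metagenes = mg,
    mixing = A,
    stabilities = iq,
    order = M,
    runs = raw$runs,
    seed = seed,
    explained_variance_fraction = wh$explained_variance_fraction,
    component_stats = stats_tbl,
    run_log = raw$run_log,
    centrotype_index = cent$centrotype_index[ord],
    control = control,
    raw = if (keep_raw) raw else NULL
  ), class = "ica_decomposition")
}

length_samples <- function(X) ncol(as_expression_values(X))

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> M = %d (%d runs), %d genes x %d samples\n",
              x$order, x$runs, ncol(x$metagenes), nrow(x$mixing)))
  cat(sprintf("  stability: %.3f (top) .. %.3f (bottom), mean %.3f\n",
              x$stabilities[1], x$stabilities[x$order], mean(x$stabilities)))
  cat(sprintf("  explained variance fraction: %.3f\n",
              x$explained_variance_fraction))
  invisible(x)
}

#' Extract the metagene matrix of a decomposition
#'
#' @param x An `ica_decomposition`, or any components x genes matrix with
#'   gene ids as column names (returned unchanged).
#' @return Matrix of standardized, oriented metagenes (components x genes).
#' @export
metagenes <- function(x) {
  if (inherits(x, "ica_decomposition")) return(x$metagenes)
  if (is.matrix(x) && is.numeric(x) && !is.null(colnames(x))) return(x)
  stop("expected an ica_decomposition or a components x genes matrix",
       call. = FALSE)
}
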