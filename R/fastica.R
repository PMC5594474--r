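#' Control parameters for the fastICA core
#'
#' @param fun Contrast nonlinearity; only `"pow3"` (cube, kurtosis-seeking) is
#'   provided — the standard choice for super-gaussian transcriptomic sources.
#' @param tol Convergence tolerance on the rotation update (default `1e-4`,
#'   the canonical fastICA default).
#' @param max_iter Maximum fixed-point iterations per run (default 200, a
#'   desk-scale setting; raise towards 1000 for production analyses). Above
#'   the effective data dimension the noise subspace has a nearly flat pow3
#'   contrast and runs routinely use the full budget — those runs are kept
#'   and flagged, and surface downstream as low-stability components, which
#'   is the signal the MSTD criterion relies on.
#' @param retry_budget How many fresh restarts a failed (degenerate output,
#'   or non-converged under `nonconvergence = "error"`) run is granted
#'   (default 5).
#' @param nonconvergence What to do with a run that exhausts `max_iter`:
#'   `"keep"` (default) retains the final estimate and flags the run in the
#'   run log; `"error"` retries it up to `retry_budget` times and aborts,
#'   listing the failing runs, if none converge.
#' @param linkage Agglomeration method for component clustering:
#'   `"average"` (default, icasso practice) or `"complete"`.
#' @param centrotype How the representative of a component cluster is chosen:
#'   `"member"` (default; the existing member with maximal total within-cluster
#'   absolute correlation) or `"mean"` (sign-aligned average of the members).
#' @param orientation_sd Tail threshold, in standard deviations of the
#'   standardized weight vector, used when orienting components (default 3).
#' @return A list of class `ica_control`.
#' @export
ica_control <- function(fun = "pow3", tol = 1e-4, max_iter = 200L,
                        retry_budget = 5L,
                        nonconvergence = c("keep", "error"),
                        linkage = c("average", "complete"),
                        centrotype = c("member", "mean"),
                        orientation_sd = 3) {
  fun <- match.arg(fun, "pow3")
  structure(list(fun = fun, tol = tol, max_iter = as.integer(max_iter),
                 retry_budget = as.integer(retry_budget),
                 nonconvergence = match.arg(nonconvergence),
                 linkage = match.arg(linkage),
                 centrotype = match.arg(centrotype),
                 orientation_sd = orientation_sd),
            class = "ica_control")
}

# Symmetric (parallel) fastICA fixed point with the pow3 contrast on a
# whitened M x N matrix Z. The random initial rotation is drawn in R (so the
# seed contract is R's RNG); the iteration runs in compiled code. Returns the
# orthogonal unmixing rotation W (M x M), i.e. the estimated sources are
# S = W %*% Z.
fastica_pow3 <- function(Z, seed, tol = 1e-4, max_iter = 200L) {
  M <- nrow(Z)
  W0 <- with_preserved_seed(seed, matrix(stats::rnorm(M * M), M, M))
  .fastica_pow3_core(Z, W0, tol, as.integer(max_iter))
}

# W <- (W W^T)^{-1/2} W via eigendecomposition (symmetric decorrelation).
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  e$vectors %*% ((1 / sqrt(vals)) * t(e$vectors)) %*% W
}

#' Run fastICA many times from random initializations
#'
#' The per-M core of the stabilization protocol: `K` fastICA fits of order `M`
#' from distinct random initializations, each seeded deterministically from the
#' master seed. Non-converged runs are retried with fresh sub-seeds up to
#' `control$retry_budget` restarts; runs still non-converged after the budget
#' abort with an error listing them.
#'
#' @param X An [expression_matrix()], or a `whitened_data` object from
#'   [whiten_reduce()] (in which case `M` must match).
#' @param M Decomposition order (number of components).
#' @param K Number of independent fastICA runs (the study protocol uses 100).
#' @param seed Master seed; sub-seeds are derived with [derive_seeds()].
#' @param control An [ica_control()].
#' @return A `raw_component_set`: `components` ((K*M) x genes gene-space
#'   weight rows, unit norm), `components_whitened` ((K*M) x M rotation rows),
#'   `run_index` (0-based run of origin per row), `order`, `runs`, `seed`,
#'   `run_log` (per-run convergence tibble) and the `whitening` used.
#' @export
run_multi_ica <- function(X, M, K = 100L, seed = 1L, control = ica_control()) {
  stopifnot(K >= 2)
  wh <- if (inherits(X, "whitened_data")) {
    if (X$M != M) stop("whitened data has M = ", X$M, ", not ", M, call. = FALSE)
    X
  } else {
    whiten_reduce(X, M)
  }
  K <- as.integer(K)
  M <- as.integer(M)
  seeds <- derive_seeds(seed, K * (control$retry_budget + 1L))
  comps_w <- matrix(NA_real_, K * M, M)
  run_index <- rep(seq_len(K) - 1L, each = M)
  log_rows <- vector("list", K)
  failed <- integer(0)
  si <- 0L
  for (k in seq_len(K)) {
    fit <- NULL
    attempts <- 0L
    repeat {
      si <- si + 1L
      attempts <- attempts + 1L
      fit <- fastica_pow3(wh$Z, seed = seeds[si], tol = control$tol,
                          max_iter = control$max_iter)
      ok <- all(is.finite(fit$W)) &&
        (fit$converged || control$nonconvergence == "keep")
      if (ok || attempts > control$retry_budget) break
    }
    if (!all(is.finite(fit$W)) ||
        (!fit$converged && control$nonconvergence == "error")) {
      failed <- c(failed, k)
    }
    comps_w[(k - 1L) * M + seq_len(M), ] <- fit$W
    log_rows[[k]] <- tibble::tibble(run = k - 1L, attempts = attempts,
                                    iterations = fit$iterations,
                                    converged = fit$converged)
  }
  if (length(failed) > 0L) {
    stop("fastICA failed to converge after ", control$retry_budget,
         " retries in run(s): ", paste(failed - 1L, collapse = ", "),
         call. = FALSE)
  }
  comps_g <- comps_w %*% wh$Z                   # gene-space projections
  comps_g <- comps_g / sqrt(rowSums(comps_g^2)) # unit norm before clustering
  colnames(comps_g) <- wh$gene_ids
  structure(list(
    components = comps_g,
    components_whitened = comps_w,
    run_index = run_index,
    order = M,
    runs = K,
    seed = seed,
    run_log = dplyr::bind_rows(log_rows),
    whitening = wh
  ), class = "raw_component_set")
}

#' @export
print.raw_component_set <- function(x, ...) {
  cat(sprintf("<raw_component_set> %d runs x %d components (%d genes)\n",
              x$runs, x$order, ncol(x$components)))
  invisible(x)
}
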