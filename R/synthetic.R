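#' Configuration for the synthetic expression generator
#'
#' The generator emulates the statistical structure stabilized ICA assumes in
#' log-scale transcriptomes: a modest number of latent transcriptional
#' programs, each loading a sparse module of genes with heavy-tailed
#' (super-gaussian, Laplace) weights, mixed across samples by gaussian
#' loadings, plus isotropic gaussian measurement noise. Optionally some
#' sources are "small-gene-set" components: one to three genes carrying
#' extreme weights, mirroring the single-gene-driven components of
#' over-decomposed regimes.
#'
#' @param n_genes,n_samples Matrix dimensions (defaults 2000 x 200).
#' @param k_sources Number of latent sources (default 10); must be below
#'   `min(n_genes, n_samples)`.
#' @param source_sparsity Fraction of genes loaded per source, in `(0, 1]`
#'   (default 0.05).
#' @param loading_scale Standard deviation of the gaussian sample loadings
#'   (default 1).
#' @param noise_sd Standard deviation of the additive gaussian noise
#'   (default 0.1).
#' @param n_small_geneset_components How many sources are small-gene-set
#'   drivers (default 0).
#' @param seed Seed making the fixture fully deterministic.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000L, n_samples = 200L,
                             k_sources = 10L, source_sparsity = 0.05,
                             loading_scale = 1, noise_sd = 0.1,
                             n_small_geneset_components = 0L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              k_sources = as.integer(k_sources),
              source_sparsity = source_sparsity,
              loading_scale = loading_scale, noise_sd = noise_sd,
              n_small_geneset_components = as.integer(n_small_geneset_components),
              seed = as.integer(seed))
  stopifnot(cfg$k_sources < min(cfg$n_genes, cfg$n_samples),
            cfg$source_sparsity > 0, cfg$source_sparsity <= 1,
            cfg$loading_scale > 0, cfg$noise_sd >= 0,
            cfg$n_small_geneset_components >= 0,
            cfg$n_small_geneset_components <= cfg$k_sources)
  n_load <- max(2L, round(cfg$source_sparsity * cfg$n_genes))
  if (n_load * cfg$k_sources > cfg$n_genes) {
    stop("infeasible sparsity: ", cfg$k_sources, " sources x ", n_load,
         " genes exceed the ", cfg$n_genes, "-gene universe", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

rlaplace <- function(n, scale = 1) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Generate synthetic expression data with planted sources
#'
#' Draws `X = t(A S) + E`: `S` (`k_sources` x genes) sparse Laplace-weighted
#' source metagenes, `A` (samples x `k_sources`) gaussian mixing, `E`
#' isotropic gaussian noise; returned genes x samples as an
#' [expression_matrix()] shifted to a positive log-scale-like baseline
#' (shifting by a constant does not affect any centered computation).
#'
#' @param cfg A [generator_config()].
#' @return List: `X` (expression matrix), `metagenes_true` (k x genes, rows
#'   standardized to zero mean and unit variance for direct comparison with
#'   recovered metagenes), `mixing_true` (samples x k), `snr` (realized
#'   signal-to-noise variance ratio; `Inf` when `noise_sd = 0`), `config`.
#' @export
generate_factor_data <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  with_preserved_seed(cfg$seed, {
    n_load <- max(2L, round(cfg$source_sparsity * cfg$n_genes))
    S <- matrix(0, cfg$k_sources, cfg$n_genes)
    n_plain <- cfg$k_sources - cfg$n_small_geneset_components
    # disjoint gene modules keep the true sources near-orthogonal
    pool <- sample.int(cfg$n_genes)
    used <- 0L
    for (k in seq_len(cfg$k_sources)) {
      if (k <= n_plain) {
        genes <- pool[used + seq_len(n_load)]
        used <- used + n_load
        S[k, genes] <- rlaplace(n_load)
      } else {
        # small-gene-set driver: 1-3 genes with extreme weights
        sz <- ((k - n_plain - 1L) %% 3L) + 1L
        genes <- pool[used + seq_len(sz)]
        used <- used + sz
        S[k, genes] <- stats::runif(sz, 10, 14)
      }
    }
    A <- matrix(stats::rnorm(cfg$n_samples * cfg$k_sources,
                             sd = cfg$loading_scale),
                cfg$n_samples, cfg$k_sources)
    signal <- t(A %*% S)                      # genes x samples
    noise <- if (cfg$noise_sd > 0) {
      matrix(stats::rnorm(length(signal), sd = cfg$noise_sd), nrow(signal))
    } else {
      0
    }
    values <- signal + noise + 8              # positive log-scale baseline
    gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
    sample_ids <- sprintf("sample_%03d", seq_len(cfg$n_samples))
    dimnames(values) <- list(gene_ids, sample_ids)
    S_std <- t(apply(S, 1L, function(w) (w - mean(w)) / stats::sd(w)))
    dimnames(S_std) <- list(paste0("source_", seq_len(cfg$k_sources)), gene_ids)
    dimnames(A) <- list(sample_ids, rownames(S_std))
    snr <- if (cfg$noise_sd > 0) {
      stats::var(as.numeric(signal)) / cfg$noise_sd^2
    } else {
      Inf
    }
    # heavy Laplace tails can exceed the log-scale heuristic bound by design
    X <- suppressWarnings(expression_matrix(values))
    list(X = X, metagenes_true = S_std,
         mixing_true = A, snr = snr, config = cfg)
  })
}

#' Generate a perfect-cluster component set
#'
#' The analytic fixture for the stability index: `M` orthonormal, zero-mean
#' gene-weight vectors, each replicated across `K` runs with random sign
#' flips. Within a planted cluster every pair has `|r| = 1` exactly; across
#' clusters the Pearson correlation is exactly 0 (the vectors are orthogonal
#' and mean-free), so every cluster's stability index equals 1.
#'
#' @param M Number of distinct components (clusters).
#' @param K Number of runs (replicates per component).
#' @param n_genes Gene-space dimension (`>= M + 1`).
#' @param seed Seed.
#' @return A `raw_component_set` (as from [run_multi_ica()], without
#'   whitening) with an extra `labels` field holding the planted cluster of
#'   each of the `K * M` rows.
#' @export
generate_perfect_clusters <- function(M, K, n_genes = 200L, seed = 1L) {
  stopifnot(M >= 1L, K >= 1L, n_genes >= M + 1L)
  with_preserved_seed(seed, {
    G <- matrix(stats::rnorm(n_genes * M), n_genes, M)
    G <- sweep(G, 2L, colMeans(G))          # span within the mean-free subspace
    Q <- qr.Q(qr(G))[, seq_len(M), drop = FALSE]
    comps <- matrix(NA_real_, K * M, n_genes)
    labels <- integer(K * M)
    signs <- sample(c(-1, 1), K * M, replace = TRUE)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * M + seq_len(M)
      comps[rows, ] <- t(Q) * signs[rows]
      labels[rows] <- seq_len(M)
    }
    colnames(comps) <- sprintf("gene_%04d", seq_len(n_genes))
    structure(list(
      components = comps,
      components_whitened = NULL,
      run_index = rep(seq_len(K) - 1L, each = M),
      order = as.integer(M),
      runs = as.integer(K),
      seed = seed,
      run_log = NULL,
      whitening = NULL,
      labels = labels
    ), class = "raw_component_set")
  })
}

#' Generate labeled points along two lines
#'
#' Fixture for the two-line clustering: points sampled along two configured
#' lines with gaussian noise applied orthogonally to each line. The analytic
#' intersection of the generating lines is returned for comparison with the
#' fitted one.
#'
#' @param line1,line2 Numeric `c(slope, intercept)` of the generating lines
#'   (distinct slopes).
#' @param n_per_line Points per line (default 30).
#' @param noise_sd Orthogonal gaussian noise standard deviation (default 0).
#' @param x_range1,x_range2 Abscissa ranges sampled per line.
#' @param seed Seed.
#' @return List: `points` tibble (`x`, `y`, `line` label) and
#'   `intersection` `c(x, y)` of the noiseless lines.
#' @export
generate_two_line_points <- function(line1, line2, n_per_line = 30L,
                                     noise_sd = 0, x_range1 = c(0, 10),
                                     x_range2 = c(0, 10), seed = 1L) {
  stopifnot(line1[1] != line2[1])
  with_preserved_seed(seed, {
    one <- function(ln, xr, label) {
      x <- stats::runif(n_per_line, xr[1], xr[2])
      y <- ln[1] * x + ln[2]
      if (noise_sd > 0) {
        normal <- c(-ln[1], 1) / sqrt(1 + ln[1]^2)
        off <- stats::rnorm(n_per_line, sd = noise_sd)
        x <- x + off * normal[1]
        y <- y + off * normal[2]
      }
      tibble::tibble(x = x, y = y, line = label)
    }
    xi <- (line2[2] - line1[2]) / (line1[1] - line2[1])
    list(points = dplyr::bind_rows(one(line1, x_range1, 1L),
                                   one(line2, x_range2, 2L)),
         intersection = c(x = xi, y = line1[1] * xi + line1[2]))
  })
}

#' Generate a synthetic two-regime stability scan
#'
#' Builds a `stability_scan` whose overlaid profile points follow two
#' analytic line regimes — near-flat high stability up to a planted dimension
#' and a distinct declining regime beyond it — with optional gaussian noise.
#' Used to validate [estimate_mstd()] against a known intersection without
#' running ICA.
#'
#' @param k_true Planted dimension (intersection abscissa of the regimes).
#' @param orders Orders to emulate (default `2:(3 * k_true)`).
#' @param flat_level Stability of the stable regime at rank 0 (default 0.95).
#' @param flat_slope Slope of the stable regime (default -0.002).
#' @param steep_slope Slope of the declining regime (default -0.03).
#' @param noise_sd Gaussian noise added to every stability value (default 0).
#' @param seed Seed.
#' @return A `stability_scan`.
#' @export
generate_two_regime_scan <- function(k_true, orders = NULL, flat_level = 0.95,
                                     flat_slope = -0.002, steep_slope = -0.03,
                                     noise_sd = 0, seed = 1L) {
  if (is.null(orders)) orders <- 2:(3 * k_true)
  with_preserved_seed(seed, {
    x_cross <- k_true
    y_cross <- flat_level + flat_slope * x_cross
    profiles <- lapply(orders, function(M) {
      r <- seq_len(M)
      y <- ifelse(r <= x_cross, flat_level + flat_slope * r,
                  y_cross + steep_slope * (r - x_cross))
      # noise jitters the point cloud without re-sorting: sorting iid noise
      # would shift the elbow rightward by order statistics and move the
      # planted intersection, defeating the fixture's purpose
      y <- pmax(y + stats::rnorm(M, sd = noise_sd), 0)
      structure(list(order = M, stabilities = y, S_total = mean(y)),
                class = "stability_profile")
    })
    structure(list(profiles = profiles, grid = as.integer(orders),
                   requested_grid = as.integer(orders), cap_applied = FALSE,
                   failed_orders = integer(0), K = NA_integer_, seed = seed),
              class = "stability_scan")
  })
}
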