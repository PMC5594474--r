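test_that("perfect component clusters score a stability index of 1", {
  pc <- generate_perfect_clusters(M = 5, K = 8, n_genes = 60, seed = 3)
  corr <- component_correlations(pc)
  # construction check: |r| = 1 inside planted clusters, 0 across
  for (m in 1:5) {
    inside <- which(pc$labels == m)
    expect_equal(abs(corr[inside, inside]), matrix(1, 8, 8),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(corr[inside, -inside],
                 matrix(0, 8, 32), tolerance = 1e-10, ignore_attr = TRUE)
  }
  cl <- cluster_components(pc)
  iq <- stability_index(cl)
  expect_equal(unname(iq), rep(1, 5), tolerance = 1e-12)
  # clustering recovers the planted labels (up to label permutation)
  tab <- table(cl$assignments, pc$labels)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("stability index matches the double-summation oracle on random partitions", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    m <- sample(2:min(6, n - 1), 1)
    V <- matrix(rnorm(n * 40), n, 40)
    corr <- cor(t(V))
    clusters <- random_partition(n, m)
    got <- stability_index(clusters, corr = corr)
    want <- stability_index_oracle(clusters, corr)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_true(all(got <= 1 + 1e-12))
  }
})

test_that("a single-cluster partition has no between-cluster term", {
  pc <- generate_perfect_clusters(M = 1, K = 6, n_genes = 40, seed = 5)
  cl <- cluster_components(pc)
  expect_identical(length(cl$clusters), 1L)
  expect_equal(unname(stability_index(cl)), 1, tolerance = 1e-12)
})

test_that("average stability handles top-k and full profiles", {
  expect_equal(average_stability(c(1.0, 0.5, 0.3), "all"), 0.6)
  expect_equal(average_stability(c(1.0, 0.5, 0.3), 1), 1.0)
  expect_equal(average_stability(c(0.7, 0.7, 0.7), 2), 0.7)
  expect_error(average_stability(c(1, 0.5), 3), "k must be")
})

test_that("centrotype is the member with maximal within-cluster similarity", {
  # cluster of 3: two near-identical members and one outlier; enumerate the
  # three candidate similarity sums by hand
  set.seed(7)
  base <- rnorm(50)
  m1 <- base + rnorm(50, sd = 0.01)
  m2 <- base + rnorm(50, sd = 0.01)
  m3 <- rnorm(50)
  comps <- rbind(m1 / sqrt(sum(m1^2)), m2 / sqrt(sum(m2^2)),
                 m3 / sqrt(sum(m3^2)))
  colnames(comps) <- sprintf("g%02d", 1:50)
  raw <- structure(list(components = comps, run_index = 0:2, order = 1L,
                        runs = 3L, seed = 1L), class = "raw_component_set")
  corr <- cor(t(comps))
  clustering <- structure(list(assignments = rep(1L, 3),
                               clusters = list(`1` = 1:3), corr = corr,
                               order = 1L),
                          class = "component_clustering")
  cent <- extract_centrotypes(clustering, raw)
  sums <- rowSums(abs(corr))
  expect_identical(cent$centrotype_index, which.max(sums))
  expect_true(cent$centrotype_index %in% 1:2) # not the outlier
})

test_that("orientation puts the heaviest tail on the positive side", {
  set.seed(12)
  w <- c(rnorm(200), -10)
  names(w) <- sprintf("g%03d", seq_along(w))
  o <- orient_component(w)
  expect_gt(o[201], 3) # the outlier flipped positive
  expect_equal(mean(o), 0, tolerance = 1e-12)
  expect_equal(sd(o), 1, tolerance = 1e-12)
  # idempotent
  expect_equal(orient_component(o), o, tolerance = 1e-12)
  # exactly symmetric vector is standardized but not flipped
  v <- c(-5, -1, 0, 1, 5)
  expect_equal(sign(orient_component(v)), c(-1, -1, 0, 1, 1))
  expect_error(orient_component(rep(2, 10)), "constant")
})

test_that("stabilized decomposition is deterministic with ordered, oriented output", {
  sim <- generate_factor_data(
    generator_config(n_genes = 250, n_samples = 50, k_sources = 4,
                     source_sparsity = 0.12, seed = 17))
  dec1 <- decompose_stabilized(sim$X, M = 4, K = 8, seed = 9)
  dec2 <- decompose_stabilized(sim$X, M = 4, K = 8, seed = 9)
  expect_identical(dec1$metagenes, dec2$metagenes)
  expect_identical(dec1$mixing, dec2$mixing)

  expect_true(all(diff(dec1$stabilities) <= 1e-12))
  # every metagene is standardized and already oriented
  expect_equal(unname(rowMeans(dec1$metagenes)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(dec1$metagenes, 1, sd)), rep(1, 4), tolerance = 1e-10)
  for (i in 1:4) {
    expect_equal(orient_component(dec1$metagenes[i, ]), dec1$metagenes[i, ],
                 tolerance = 1e-12)
  }
})

test_that("reconstruction error stays within the PCA truncation residual", {
  sim <- generate_factor_data(
    generator_config(n_genes = 300, n_samples = 60, k_sources = 5,
                     source_sparsity = 0.1, noise_sd = 0.2, seed = 23))
  dec <- decompose_stabilized(sim$X, M = 5, K = 6, seed = 1)
  v <- unclass(sim$X)
  vc <- v - rowMeans(v)
  vc <- sweep(vc, 2, colMeans(vc))
  resid <- sum((t(vc) - dec$mixing %*% dec$metagenes)^2) / sum(vc^2)
  expect_lte(resid, (1 - dec$explained_variance_fraction) + 1e-6)
})

test_that("planted metagenes are recovered by the stabilized decomposition", {
  sim <- generate_factor_data(
    generator_config(n_genes = 600, n_samples = 80, k_sources = 6,
                     source_sparsity = 0.08, seed = 29))
  dec <- decompose_stabilized(sim$X, M = 6, K = 10, seed = 2)
  mt <- match_sets(sim$metagenes_true, dec)
  expect_true(all(mt$abs_r > 0.9))
  expect_true(all(mt$reciprocal))
})
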