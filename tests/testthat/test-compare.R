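std <- function(w) (w - mean(w)) / sd(w)

# small standardized metagene matrix with named genes
random_metagenes <- function(n_comp, n_genes, seed, prefix = "IC") {
  set.seed(seed)
  m <- t(apply(matrix(rnorm(n_comp * n_genes), n_comp), 1, std))
  dimnames(m) <- list(paste0(prefix, seq_len(n_comp)),
                      sprintf("g%04d", seq_len(n_genes)))
  m
}

test_that("metagene correlation equals the covariance formula on common genes", {
  set.seed(2)
  a <- std(rnorm(20)); b <- std(rnorm(20))
  names(a) <- names(b) <- sprintf("g%02d", 1:20)
  r <- correlate_metagenes(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_equal(correlate_metagenes(a, a), 1, tolerance = 1e-12)
  expect_equal(correlate_metagenes(a, -a), -1, tolerance = 1e-12)
  # disjoint gene universes give the undefined sentinel, not an error
  b2 <- b; names(b2) <- sprintf("h%02d", 1:20)
  expect_identical(correlate_metagenes(a, b2), NA_real_)
})

test_that("the 3-SD restriction uses only the query's extreme genes", {
  set.seed(3)
  a <- c(rep(0.1, 96), 8, 9, -7, 10)
  names(a) <- sprintf("g%03d", seq_along(a))
  a <- std(a) * 3.5 / max(abs(std(a))) * 2 # keep the four extremes beyond 3 sd
  b <- a + rnorm(100, sd = 0.01)
  names(b) <- names(a)
  extreme <- names(a)[abs(std(a)) > 3]
  r_restricted <- correlate_metagenes(a, b, restrict_3sd = TRUE, min_genes = 2)
  oracle <- cor(a[extreme], b[extreme])
  expect_equal(r_restricted, oracle, tolerance = 1e-12)
})

test_that("matching recovers identity and planted permutations", {
  A <- random_metagenes(5, 200, seed = 7)
  self <- match_sets(A, A)
  expect_identical(self$match, rownames(A))
  expect_equal(self$r, rep(1, 5), tolerance = 1e-12)
  expect_true(all(self$reciprocal))
  expect_true(all(self$gap > 1))

  perm <- c(3, 1, 4, 5, 2)
  B <- A[perm, ]
  rownames(B) <- paste0("B", 1:5)
  mt <- match_sets(A, B)
  expect_identical(mt$match, paste0("B", order(perm)))
  expect_true(all(mt$reciprocal))

  # unrelated random sets stay below any sensible threshold
  C <- random_metagenes(5, 200, seed = 99, prefix = "C")
  null_mt <- match_sets(A, C)
  expect_true(all(null_mt$abs_r < 0.3))
})

test_that("match graphs are undirected, cross-dataset, and clique planted components", {
  shared <- random_metagenes(1, 300, seed = 1, prefix = "shared")
  decs <- lapply(1:3, function(d) {
    extra <- random_metagenes(3, 300, seed = 100 + d)
    m <- rbind(shared, extra)
    rownames(m) <- paste0("IC", 1:4)
    m
  })
  names(decs) <- paste0("ds", 1:3)
  mg <- build_match_graph(decs, threshold = 0.3)
  # the planted component forms a 3-clique
  planted <- paste0("ds", 1:3, ".IC1")
  sub <- igraph::induced_subgraph(mg$graph, planted)
  expect_equal(igraph::ecount(sub), 3)
  # no within-dataset edges
  ends <- igraph::ends(mg$graph, igraph::E(mg$graph))
  ds_of <- function(x) sub("\\..*$", "", x)
  expect_true(all(ds_of(ends[, 1]) != ds_of(ends[, 2])))
  # impossible threshold empties the graph
  mg2 <- build_match_graph(decs, threshold = 1.01)
  expect_identical(nrow(mg2$edges), 0L)
})

test_that("reproducibility scores sum reciprocal-edge correlations", {
  shared <- random_metagenes(1, 300, seed = 5, prefix = "s")
  decs <- lapply(1:4, function(d) {
    m <- rbind(shared, random_metagenes(2, 300, seed = 200 + d))
    rownames(m) <- paste0("IC", 1:3)
    m
  })
  names(decs) <- paste0("ds", 1:4)
  mg <- build_match_graph(decs)
  sc <- reproducibility_scores(mg)
  expect_true(all(sc$score <= 3 + 1e-12)) # bounded by n_datasets - 1
  planted_scores <- sc$score[sc$component == "IC1"]
  expect_equal(planted_scores, rep(3, 4), tolerance = 1e-9)
  expect_equal(reproducibility_score(mg, "ds1.IC1"), 3, tolerance = 1e-9)
  # isolated nodes score zero
  expect_true(all(sc$score[sc$degree == 0] == 0))
})

test_that("rank-score curves isolate the shared low ranks", {
  set.seed(8)
  n_shared <- 3
  shared <- random_metagenes(n_shared, 400, seed = 55, prefix = "s")
  decs <- lapply(1:3, function(d) {
    m <- rbind(shared, random_metagenes(4, 400, seed = 300 + d))
    rownames(m) <- paste0("IC", 1:7)
    m
  })
  names(decs) <- paste0("ds", 1:3)
  mg <- build_match_graph(decs)
  curve <- rank_score_curve(mg)
  expect_true(all(curve$mean_score[curve$rank <= n_shared] > 1.5))
  expect_true(all(curve$mean_score[curve$rank > n_shared] < 0.5))
  expect_true(all(curve$mean_score <= 2 + 1e-12))
  expect_error(rank_score_curve(mg, relative_to_mstd = TRUE), "mstd")
  rel <- rank_score_curve(mg, relative_to_mstd = TRUE,
                          mstd = c(ds1 = 3, ds2 = 3, ds3 = 3))
  expect_true("relative_rank" %in% names(rel))
})

test_that("conservation classes follow the split > conserved > not_conserved precedence", {
  low <- random_metagenes(4, 500, seed = 21)
  # high-order set: the low components plus orthogonal noise -> all conserved
  high <- rbind(low, random_metagenes(4, 500, seed = 22, prefix = "N"))
  rownames(high) <- paste0("H", 1:8)
  rep1 <- classify_conservation(low, high)
  expect_true(all(rep1$components$class == "conserved"))
  expect_true(all(rep1$components$high_correlation))
  expect_equal(sum(rep1$frequencies$frequency), 1)

  # one low component built as the sum of two high components -> split
  set.seed(23)
  h1 <- std(rnorm(500)); h2 <- std(rnorm(500))
  low2 <- rbind(std(h1 + h2), random_metagenes(2, 500, seed = 24))
  rownames(low2) <- paste0("L", 1:3)
  colnames(low2) <- sprintf("g%04d", 1:500)
  high2 <- rbind(h1, h2, low2[2:3, ], random_metagenes(2, 500, seed = 25))
  rownames(high2) <- paste0("H", 1:6)
  colnames(high2) <- colnames(low2)
  rep2 <- classify_conservation(low2, high2)
  expect_identical(rep2$components$class[1], "split")
  expect_identical(rep2$components$class[2:3], c("conserved", "conserved"))

  # disjoint gene universes: everything not conserved via the NA sentinel
  high3 <- high
  colnames(high3) <- sprintf("x%04d", 1:500)
  rep3 <- classify_conservation(low, high3)
  expect_true(all(rep3$components$class == "not_conserved"))
})

test_that("small-gene-set detection isolates planted drivers and spares gaussians", {
  # single dominant gene
  w1 <- planted_tail_weights(c(10), seed = 1)
  call1 <- detect_small_geneset(w1)
  expect_true(call1$driven)
  expect_identical(call1$driver_genes, names(w1)[1])

  # the worked gap sequence: 12, 4, 3.5 over a bounded remainder
  w2 <- planted_tail_weights(c(12, 4, 3.5), seed = 2)
  call2 <- detect_small_geneset(w2)
  expect_equal(unname(call2$gaps[1]), 3.0, tolerance = 1e-12)
  expect_equal(unname(call2$gaps[2]), 4 / 3.5, tolerance = 1e-12)
  expect_true(call2$driven)
  expect_identical(call2$driver_genes, names(w2)[1])

  # three-gene module separated from the bulk by the boundary gap
  w3 <- planted_tail_weights(c(9.5, 9, 8.4), seed = 3)
  call3 <- detect_small_geneset(w3)
  expect_true(call3$driven)
  expect_identical(call3$driver_genes, names(w3)[1:3])

  # negative-tail drivers are found on the heavier tail
  w4 <- -planted_tail_weights(c(11, 10), seed = 4)
  call4 <- detect_small_geneset(w4)
  expect_true(call4$driven)
  expect_identical(call4$heaviest_tail, "negative")
  expect_identical(call4$driver_genes, names(w4)[1:2])

  # pure gaussian weights are never flagged
  flags <- sapply(1:50, function(s) {
    set.seed(1000 + s)
    w <- rnorm(2000)
    names(w) <- sprintf("g%04d", seq_along(w))
    detect_small_geneset(std(w))$driven
  })
  expect_false(any(flags))
})

test_that("Jaccard of top-contributing genes follows set arithmetic", {
  w <- planted_tail_weights(c(8, 7, 6.5, 6, 5.5), seed = 6)
  top <- names(w)[w > 5]
  expect_equal(jaccard_top_genes(w, top), 1.0)
  expect_equal(jaccard_top_genes(w, c("zz1", "zz2")),
               0 / length(union(top, c("zz1", "zz2"))))
  ref <- c(top, sprintf("zz%02d", 1:(20 - length(top))))
  expect_equal(jaccard_top_genes(w, ref), length(top) / 20)
  expect_identical(jaccard_top_genes(w["g0010"], "absent"), 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # 4-gene universe, top = {a, b}, ref = {a, b}: p = 1 / C(4,2)
  m <- c(a = 6, b = 5.5, c = 0.1, d = -0.2)
  res <- hypergeom_enrich(m, list(ref = c("a", "b")), weight_floor = 5)
  expect_equal(res$p_value, 1 / choose(4, 2), tolerance = 1e-12)

  # exhaustive-enumeration oracle over all draws for small universes
  set.seed(44)
  for (rep in 1:20) {
    n_univ <- sample(6:12, 1)
    genes <- sprintf("g%02d", seq_len(n_univ))
    w <- rnorm(n_univ); names(w) <- genes
    n_top <- sample(1:4, 1)
    w[sample(n_univ, n_top)] <- 6 # lift a random subset over the floor
    ref <- sample(genes, sample(2:5, 1))
    res_i <- hypergeom_enrich(w, list(s = ref), weight_floor = 5)
    # oracle: enumerate every draw of size n_top from the universe
    draws <- combn(genes, sum(w > 5))
    k_obs <- length(intersect(names(w)[w > 5], ref))
    p_oracle <- mean(apply(draws, 2, function(d) {
      length(intersect(d, ref)) >= k_obs
    }))
    expect_equal(res_i$p_value, p_oracle, tolerance = 1e-12)
  }

  # a set covering the whole universe is trivially unenriched
  res2 <- hypergeom_enrich(m, list(all = names(m)), weight_floor = 5)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)
  expect_warning(hypergeom_enrich(m, list(off = c("zz"))), "disjoint")

  # invariant to gene ordering
  perm <- sample(length(m))
  res3 <- hypergeom_enrich(m[perm], list(ref = c("a", "b")), weight_floor = 5)
  expect_equal(res3$p_value, res$p_value, tolerance = 1e-15)

  # BH correction across several sets
  sets <- list(s1 = c("a", "b"), s2 = c("c", "d"), s3 = c("a", "d"))
  res4 <- hypergeom_enrich(m, sets, weight_floor = 5)
  expect_equal(res4$p_adjusted,
               p.adjust(res4$p_value, method = "BH"), tolerance = 1e-15)
})
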