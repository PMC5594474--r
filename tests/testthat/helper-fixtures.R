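# Small reusable fixtures, all generated in code.

# Tiny deterministic expression matrix with named ids.
tiny_expression <- function(n_genes = 30L, n_samples = 12L, seed = 42L) {
  set.seed(seed)
  values <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2),
                   n_genes, n_samples)
  expression_matrix(values,
                    gene_ids = sprintf("g%03d", seq_len(n_genes)),
                    sample_ids = sprintf("s%02d", seq_len(n_samples)))
}

# Standardized weight vector with a planted heavy positive tail, the rest
# gaussian bounded away from the tail threshold.
planted_tail_weights <- function(tail_values, n_rest = 500L, rest_cap = 2.8,
                                 seed = 1L) {
  set.seed(seed)
  rest <- rnorm(n_rest)
  rest <- pmin(pmax(rest, -rest_cap), rest_cap)
  w <- c(tail_values, rest)
  names(w) <- sprintf("g%04d", seq_along(w))
  w
}

# Literal double-summation implementation of the cluster stability index,
# kept deliberately naive as the oracle for the vectorised version.
stability_index_oracle <- function(clusters, corr) {
  n <- nrow(corr)
  sapply(clusters, function(Ck) {
    intra <- 0
    for (i in Ck) for (j in Ck) intra <- intra + abs(corr[i, j])
    intra <- intra / length(Ck)^2
    outside <- setdiff(seq_len(n), Ck)
    if (length(outside) == 0L) return(intra)
    inter <- 0
    for (i in Ck) for (j in outside) inter <- inter + abs(corr[i, j])
    intra - inter / (length(Ck) * length(outside))
  })
}

# Random partition of n items into m non-empty clusters.
random_partition <- function(n, m) {
  labels <- c(seq_len(m), sample.int(m, n - m, replace = TRUE))
  split(seq_len(n), sample(labels))
}
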