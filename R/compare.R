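#' Correlate two metagenes over their common genes
#'
#' Pearson correlation between the gene weights of two metagenes, computed on
#' the genes present in both. With `restrict_3sd = TRUE` only genes whose
#' standardized weight in the query metagene `a` exceeds 3 standard deviations
#' in absolute value enter the correlation (the convention used when matching
#' a newly identified component against reference metagenes). When fewer than
#' `min_genes` genes remain the match is undefined and `NA` is returned
#' rather than an error.
#'
#' @param a,b Named numeric weight vectors (standardized, oriented).
#' @param restrict_3sd Restrict to the query's 3-standard-deviation genes.
#' @param min_genes Minimum number of common genes (default 10).
#' @return Signed Pearson `r`, or `NA_real_` when undefined.
#' @export
correlate_metagenes <- function(a, b, restrict_3sd = FALSE, min_genes = 10L) {
  common <- intersect(names(a), names(b))
  if (restrict_3sd) {
    za <- (a - mean(a)) / stats::sd(a)
    common <- intersect(names(a)[abs(za) > 3], common)
  }
  if (length(common) < min_genes) return(NA_real_)
  x <- a[common]; y <- b[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Cross-correlation matrix between two metagene matrices (rows = components)
# over common genes; rows of the result are queries from A. With the 3-sd
# restriction the gene subset differs per query row.
cross_correlations <- function(A, B, restrict_3sd = FALSE, min_genes = 10L) {
  common <- intersect(colnames(A), colnames(B))
  R <- matrix(NA_real_, nrow(A), nrow(B),
              dimnames = list(rownames(A), rownames(B)))
  if (length(common) < min_genes && !restrict_3sd) return(R)
  if (!restrict_3sd) {
    if (length(common) >= min_genes) {
      R[] <- suppressWarnings(stats::cor(t(A[, common, drop = FALSE]),
                                         t(B[, common, drop = FALSE])))
      R[!is.finite(R)] <- NA_real_
    }
    return(R)
  }
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      R[i, j] <- correlate_metagenes(A[i, ], B[j, ], restrict_3sd = TRUE,
                                     min_genes = min_genes)
    }
  }
  R
}

#' Match two sets of metagenes
#'
#' For every query metagene in `A`, the best-matched target in `B` is the one
#' maximizing the absolute Pearson correlation over common genes. A pair is
#' reciprocal when the argmax holds in both directions. The `gap` is the
#' ratio of the best to the second-best absolute correlation (`Inf` when `B`
#' has a single component); large gaps mean well-separable matches.
#'
#' @param A,B Metagene matrices (components x genes with ids as dimnames) or
#'   `ica_decomposition` objects.
#' @param restrict_3sd,min_genes Passed to [correlate_metagenes()].
#' @return Tibble with one row per query: `query`, `match`, `r`, `abs_r`,
#'   `gap`, `reciprocal`. Queries with no defined correlation get `NA`
#'   matches.
#' @export
match_sets <- function(A, B, restrict_3sd = FALSE, min_genes = 10L) {
  A <- metagenes(A); B <- metagenes(B)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty metagene set", call. = FALSE)
  R_ab <- cross_correlations(A, B, restrict_3sd, min_genes)
  R_ba <- if (restrict_3sd) {
    cross_correlations(B, A, restrict_3sd, min_genes)
  } else {
    t(R_ab)
  }
  best_of <- function(R) {
    apply(R, 1L, function(row) {
      if (all(is.na(row))) NA_integer_ else which.max(abs(row))
    })
  }
  best_ab <- best_of(R_ab)
  best_ba <- best_of(R_ba)
  rows <- lapply(seq_len(nrow(A)), function(i) {
    j <- best_ab[i]
    if (is.na(j)) {
      return(tibble::tibble(query = rownames(A)[i], match = NA_character_,
                            r = NA_real_, abs_r = NA_real_, gap = NA_real_,
                            reciprocal = FALSE))
    }
    a <- abs(R_ab[i, ])
    second <- if (length(a) > 1L) max(a[-j], na.rm = TRUE) else NA_real_
    gap <- if (!is.finite(second) || second == 0) Inf else a[j] / second
    tibble::tibble(
      query = rownames(A)[i],
      match = rownames(B)[j],
      r = R_ab[i, j],
      abs_r = abs(R_ab[i, j]),
      gap = gap,
      reciprocal = !is.na(best_ba[j]) && best_ba[j] == i
    )
  })
  dplyr::bind_rows(rows)
}

#' Build a reciprocal-correlation graph across datasets
#'
#' All-pairs metagene matching between two or more decompositions; nodes are
#' components, edges connect reciprocal best-matched pairs from different
#' datasets whose absolute correlation exceeds `threshold` (default 0.3).
#' Edge weight is `|r|`; the signed correlation is kept as an attribute.
#'
#' @param decs Named list of metagene matrices or `ica_decomposition`s, one
#'   per dataset.
#' @param threshold Minimum absolute reciprocal correlation for an edge.
#' @param restrict_3sd,min_genes Passed to [match_sets()].
#' @return A `match_graph`: `graph` (undirected igraph with vertex attributes
#'   `dataset`, `component`, `rank`, `stability` and edge attributes `r`,
#'   `abs_r`/`weight`), `nodes` and `edges` tibbles, `threshold`.
#' @export
build_match_graph <- function(decs, threshold = 0.3, restrict_3sd = FALSE,
                              min_genes = 10L) {
  if (length(decs) < 2L) stop("need at least 2 datasets", call. = FALSE)
  if (is.null(names(decs)) || any(!nzchar(names(decs)))) {
    names(decs) <- paste0("dataset", seq_along(decs))
  }
  mats <- lapply(decs, metagenes)
  nodes <- dplyr::bind_rows(lapply(names(mats), function(ds) {
    m <- mats[[ds]]
    st <- if (inherits(decs[[ds]], "ica_decomposition")) {
      decs[[ds]]$component_stats
    } else NULL
    tibble::tibble(
      name = paste(ds, rownames(m), sep = "."),
      dataset = ds,
      component = rownames(m),
      rank = seq_len(nrow(m)),
      stability = if (!is.null(st)) st$stability else NA_real_,
      kurtosis = if (!is.null(st)) st$kurtosis else NA_real_,
      variance_share = if (!is.null(st)) st$variance_share else NA_real_
    )
  }))
  edge_rows <- list()
  ds <- names(mats)
  for (i in seq_along(ds)) {
    for (j in seq_along(ds)) {
      if (j <= i) next
      mt <- match_sets(mats[[ds[i]]], mats[[ds[j]]],
                       restrict_3sd = restrict_3sd, min_genes = min_genes)
      keep <- dplyr::filter(mt, .data$reciprocal, .data$abs_r > threshold)
      if (nrow(keep) > 0L) {
        edge_rows[[length(edge_rows) + 1L]] <- tibble::tibble(
          from = paste(ds[i], keep$query, sep = "."),
          to = paste(ds[j], keep$match, sep = "."),
          r = keep$r,
          abs_r = keep$abs_r
        )
      }
    }
  }
  edges <- if (length(edge_rows) > 0L) dplyr::bind_rows(edge_rows) else {
    tibble::tibble(from = character(), to = character(),
                   r = numeric(), abs_r = numeric())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (igraph::ecount(g) > 0L) {
    igraph::E(g)$weight <- igraph::E(g)$abs_r
  }
  structure(list(graph = g, nodes = nodes, edges = edges,
                 threshold = threshold),
            class = "match_graph")
}

#' @export
print.match_graph <- function(x, ...) {
  cat(sprintf("<match_graph> %d components, %d reciprocal edges (|r| > %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Export a match graph to GraphML
#'
#' @param mg A `match_graph`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_match_graph <- function(mg, path) {
  g <- mg$graph
  for (at in igraph::vertex_attr_names(g)) {
    if (all(is.na(igraph::vertex_attr(g, at)))) {
      g <- igraph::delete_vertex_attr(g, at)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Reproducibility scores of all components in a match graph
#'
#' The reproducibility score of a component is the sum of the absolute
#' correlation coefficients on its reciprocal edges to components of other
#' datasets. With `D` datasets it is bounded by `D - 1`; a component planted
#' identically in every dataset scores exactly `D - 1`.
#'
#' @param mg A `match_graph`.
#' @return Tibble: `name`, `dataset`, `component`, `rank`, `stability`,
#'   `score`, `degree`.
#' @export
reproducibility_scores <- function(mg) {
  g <- mg$graph
  score <- igraph::strength(g, weights = igraph::E(g)$abs_r)
  deg <- igraph::degree(g)
  dplyr::mutate(mg$nodes,
                score = as.numeric(score[.data$name]),
                degree = as.integer(deg[.data$name]))
}

#' @rdname reproducibility_scores
#' @param node Node name (`"<dataset>.<component>"`).
#' @return `reproducibility_score()` returns the single score as a number.
#' @export
reproducibility_score <- function(mg, node) {
  sc <- reproducibility_scores(mg)
  hit <- sc$score[sc$name == node]
  if (length(hit) == 0L) stop("node not in graph: ", node, call. = FALSE)
  hit
}

#' Mean reproducibility score as a function of component rank
#'
#' The diagnostic behind comparing ranking schemes: group components by their
#' rank under the chosen ranking (stability, kurtosis, or explained
#' variance), optionally relative to each dataset's MSTD, and average the
#' reproducibility scores.
#'
#' @param mg A `match_graph` built from decompositions (so nodes carry
#'   stability/kurtosis/variance values).
#' @param ranking One of `"stability"`, `"kurtosis"`, `"variance"`.
#' @param relative_to_mstd Use `rank - MSTD(dataset)` instead of the absolute
#'   rank (only meaningful for the stability ranking).
#' @param mstd Named numeric vector of MSTD values per dataset; required when
#'   `relative_to_mstd = TRUE`.
#' @return Tibble with `rank` (or `relative_rank`), `mean_score`, `n`.
#' @export
rank_score_curve <- function(mg, ranking = c("stability", "kurtosis", "variance"),
                             relative_to_mstd = FALSE, mstd = NULL) {
  ranking <- match.arg(ranking)
  sc <- reproducibility_scores(mg)
  key <- switch(ranking, stability = "stability", kurtosis = "kurtosis",
                variance = "variance_share")
  sc <- dplyr::group_by(sc, .data$dataset)
  sc <- dplyr::mutate(sc, use_rank = if (ranking == "stability") {
    .data$rank
  } else {
    rank(-abs(.data[[key]]), ties.method = "first")
  })
  sc <- dplyr::ungroup(sc)
  if (relative_to_mstd) {
    if (is.null(mstd)) {
      stop("`mstd` values per dataset are required when relative_to_mstd = TRUE",
           call. = FALSE)
    }
    sc <- dplyr::mutate(sc,
                        use_rank = .data$use_rank - mstd[.data$dataset])
  }
  out <- dplyr::summarise(dplyr::group_by(sc, rank = .data$use_rank),
                          mean_score = mean(.data$score),
                          n = dplyr::n(), .groups = "drop")
  if (relative_to_mstd) out <- dplyr::rename(out, relative_rank = "rank")
  out
}

#' Classify conservation of components in a higher-order decomposition
#'
#' Compares a decomposition at (or near) the MSTD with a higher-order
#' decomposition of the same dataset. A low-order component is *conserved*
#' when it has a reciprocal best match with `|r| > threshold` in the
#' high-order set; it is *split* when, in addition, at least one other
#' high-order component points to it as its (non-reciprocal) best match with
#' `|r| > threshold` — the signature of one signal dividing into several
#' finer components; otherwise it is *not conserved*. Classes are exclusive
#' with precedence split > conserved > not_conserved.
#'
#' @param low `ica_decomposition` (or metagene matrix) at the lower order.
#' @param high The higher-order decomposition of the same dataset.
#' @param threshold Minimum absolute correlation (default 0.3, the match-graph
#'   threshold).
#' @param high_r Level reported as "high correlation" conservation
#'   (default 0.8).
#' @param restrict_3sd,min_genes Passed to [match_sets()].
#' @return A `conservation_report`: `components` tibble (`component`,
#'   `class`, `match`, `r`, `high_correlation`, `n_incoming`) and
#'   `frequencies` tibble over the three classes (summing to 1).
#' @export
classify_conservation <- function(low, high, threshold = 0.3, high_r = 0.8,
                                  restrict_3sd = FALSE, min_genes = 10L) {
  L <- metagenes(low); H <- metagenes(high)
  if (nrow(H) <= nrow(L)) {
    stop("`high` must have more components than `low`", call. = FALSE)
  }
  lh <- match_sets(L, H, restrict_3sd = restrict_3sd, min_genes = min_genes)
  hl <- match_sets(H, L, restrict_3sd = restrict_3sd, min_genes = min_genes)
  rows <- lapply(seq_len(nrow(L)), function(i) {
    comp <- rownames(L)[i]
    m <- lh[i, ]
    incoming <- dplyr::filter(hl, .data$match == comp, !.data$reciprocal,
                              .data$abs_r > threshold)
    conserved <- isTRUE(m$reciprocal) && !is.na(m$abs_r) &&
      m$abs_r > threshold
    cls <- if (conserved && nrow(incoming) >= 1L) {
      "split"
    } else if (conserved) {
      "conserved"
    } else {
      "not_conserved"
    }
    tibble::tibble(component = comp, class = cls, match = m$match, r = m$r,
                   high_correlation = !is.na(m$abs_r) && conserved &&
                     m$abs_r > high_r,
                   n_incoming = nrow(incoming))
  })
  components <- dplyr::bind_rows(rows)
  freq <- tibble::tibble(class = c("conserved", "split", "not_conserved"))
  freq$frequency <- vapply(freq$class, function(cl) {
    mean(components$class == cl)
  }, numeric(1))
  structure(list(components = components, frequencies = freq,
                 threshold = threshold, high_r = high_r),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %d components (|r| > %.2f)\n",
              nrow(x$components), x$threshold))
  for (i in seq_len(nrow(x$frequencies))) {
    cat(sprintf("  %-14s %5.1f%%\n", x$frequencies$class[i],
                100 * x$frequencies$frequency[i]))
  }
  invisible(x)
}

#' Detect a component driven by a small gene set
#'
#' Over-decomposed regimes produce components whose weight distribution is
#' dominated by one to three genes separated from the rest by a large
#' multiplicative gap. For the heavier tail of the standardized weight
#' distribution, the genes `P` with `|W| > W_top` are sorted by decreasing
#' absolute weight and the gap sequence `G_i = |W_i| / |W_{i+1}|` is
#' examined, including the boundary gap between the last gene of `P` and the
#' heaviest sub-threshold weight of the same tail. The component is called
#' driven when exactly one gap exceeds `G_max`; the driver genes are those
#' ranked at or above that unique gap.
#'
#' @param m Named standardized, oriented weight vector (a metagene row).
#' @param W_top Tail threshold on standardized weights (default 3.0).
#' @param G_max Gap threshold (default 1.5).
#' @return A `small_geneset_call`: `driven`, `driver_genes`,
#'   `heaviest_tail` (`"positive"`/`"negative"`), `tail_weights`, `gaps`,
#'   `W_top`, `G_max`.
#' @export
detect_small_geneset <- function(m, W_top = 3.0, G_max = 1.5) {
  stopifnot(!is.null(names(m)))
  pos_w <- sum(m[m > W_top])
  neg_w <- sum(-m[m < -W_top])
  tail_sign <- if (neg_w > pos_w) "negative" else "positive"
  w_tail <- if (tail_sign == "positive") m[m > 0] else -m[m < 0]
  w_tail <- sort(w_tail, decreasing = TRUE)
  P <- w_tail[w_tail > W_top]
  call_out <- function(driven, drivers, gaps) {
    structure(list(driven = driven, driver_genes = drivers,
                   heaviest_tail = tail_sign,
                   tail_weights = c(positive = pos_w, negative = neg_w),
                   gaps = gaps, W_top = W_top, G_max = G_max),
              class = "small_geneset_call")
  }
  if (length(P) == 0L) return(call_out(FALSE, character(0), numeric(0)))
  below <- w_tail[w_tail <= W_top & w_tail > 0]
  # boundary gap between the last super-threshold gene and the heaviest
  # remaining weight of the tail; an empty remainder separates perfectly
  gaps <- if (length(below) > 0L) {
    c(P, below[1])[seq_along(P)] / c(P[-1], below[1])
  } else {
    c(P[-length(P)] / P[-1], Inf)
  }
  names(gaps) <- names(P)
  over <- which(gaps > G_max)
  if (length(over) == 1L && over <= length(P)) {
    call_out(TRUE, names(P)[seq_len(over)], gaps)
  } else {
    call_out(FALSE, character(0), gaps)
  }
}

#' @export
print.small_geneset_call <- function(x, ...) {
  if (x$driven) {
    cat(sprintf("<small_geneset_call> driven by %d gene(s): %s\n",
                length(x$driver_genes), paste(x$driver_genes, collapse = ", ")))
  } else {
    cat("<small_geneset_call> not driven by a small gene set\n")
  }
  invisible(x)
}

#' Jaccard index between a component's top genes and a reference set
#'
#' `J = |T intersect ref| / |T union ref|` where `T` is the set of
#' top-contributing genes of the component — genes with positive standardized
#' weight above `weight_floor` (default 5.0).
#'
#' @param m Named standardized, oriented weight vector.
#' @param ref Character vector of reference gene ids.
#' @param weight_floor Weight threshold defining top-contributing genes.
#' @return The Jaccard index, or `NA_real_` when both sets are empty.
#' @export
jaccard_top_genes <- function(m, ref, weight_floor = 5.0) {
  top <- names(m)[m > weight_floor]
  u <- union(top, ref)
  if (length(u) == 0L) return(NA_real_)
  length(intersect(top, ref)) / length(u)
}

#' Hypergeometric enrichment of a component's top genes
#'
#' Upper-tail hypergeometric test of the overlap between the component's
#' top-contributing genes (positive weight above `weight_floor`) and each
#' reference gene set, over the universe of genes carried by the component.
#' Reference genes absent from the universe are dropped; a set fully disjoint
#' from the universe gets `p = 1` with a warning.
#'
#' @param m Named standardized, oriented weight vector.
#' @param sets A `gene_set_collection` (see [read_gmt()]) or named list of
#'   character vectors.
#' @param weight_floor Weight threshold defining top-contributing genes
#'   (default 5.0).
#' @param correction Multiple-testing correction method for [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Tibble: `set`, `n_set` (set size in universe), `n_top`, `overlap`,
#'   `p_value`, `p_adjusted`, sorted by `p_value`.
#' @export
hypergeom_enrich <- function(m, sets, weight_floor = 5.0, correction = "BH") {
  universe <- names(m)
  top <- names(m)[m > weight_floor]
  if (inherits(sets, "gene_set_collection")) {
    sets <- lapply(sets, `[[`, "genes")
  }
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (length(members) == 0L) {
      warning("gene set '", nm, "' is disjoint from the component's universe",
              call. = FALSE)
      return(tibble::tibble(set = nm, n_set = 0L, n_top = length(top),
                            overlap = 0L, p_value = 1))
    }
    k <- length(intersect(top, members))
    p <- stats::phyper(k - 1L, length(members),
                       length(universe) - length(members), length(top),
                       lower.tail = FALSE)
    tibble::tibble(set = nm, n_set = length(members), n_top = length(top),
                   overlap = k, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = correction)
  dplyr::arrange(out, .data$p_value)
}
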