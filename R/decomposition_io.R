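#' Write a stabilized decomposition to disk
#'
#' Writes `<prefix>_S.tsv` (metagenes, components x genes with a `component`
#' id column), `<prefix>_A.tsv` (mixing, samples x components with a `sample`
#' id column) and `<prefix>_meta.json` carrying the order `M`, the number of
#' runs `K`, the master `seed`, the stability indices, the explained variance
#' fraction and the control parameters — full provenance for any downstream
#' comparison.
#'
#' @param dec An `ica_decomposition`.
#' @param prefix Path prefix for the three output files.
#' @return The three paths, invisibly.
#' @export
write_decomposition <- function(dec, prefix) {
  stopifnot(inherits(dec, "ica_decomposition"))
  paths <- paste0(prefix, c("_S.tsv", "_A.tsv", "_meta.json"))
  write_numeric_table(dec$metagenes, paths[1], id_col = "component")
  write_numeric_table(dec$mixing, paths[2], id_col = "sample")
  meta <- list(
    M = dec$order,
    K = dec$runs,
    seed = dec$seed,
    stabilities = dec$stabilities,
    explained_variance_fraction = dec$explained_variance_fraction,
    control = unclass(dec$control)
  )
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a stabilized decomposition written by [write_decomposition()]
#'
#' @param prefix The path prefix used when writing.
#' @return An `ica_decomposition` (without the pooled raw components).
#' @export
read_decomposition <- function(prefix) {
  paths <- paste0(prefix, c("_S.tsv", "_A.tsv", "_meta.json"))
  if (!all(file.exists(paths))) {
    stop("missing decomposition files for prefix ", prefix, call. = FALSE)
  }
  S <- read_numeric_table(paths[1])
  A <- read_numeric_table(paths[2])
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  ctl <- do.call(ica_control, meta$control[names(meta$control) %in%
                                             names(formals(ica_control))])
  stabilities <- as.numeric(meta$stabilities)
  M <- as.integer(meta$M)
  stats_tbl <- tibble::tibble(
    component = rownames(S),
    rank = seq_len(M),
    stability = stabilities,
    kurtosis = apply(S, 1L, function(w) mean(w^4) - 3),
    variance_share = NA_real_
  )
  structure(list(
    metagenes = S,
    mixing = A,
    stabilities = stabilities,
    order = M,
    runs = as.integer(meta$K),
    seed = meta$seed,
    explained_variance_fraction = meta$explained_variance_fraction,
    component_stats = stats_tbl,
    run_log = NULL,
    centrotype_index = NULL,
    control = ctl,
    raw = NULL
  ), class = "ica_decomposition")
}
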