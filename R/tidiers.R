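#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style tidiers for stabilized-ICA result objects
#'
#' `tidy()` returns the per-element table of a result (component statistics,
#' profile points, graph edges, conservation calls); `glance()` returns a
#' one-row summary.
#'
#' @param x A result object.
#' @param matrix For `ica_decomposition`: `"stats"` (default) for component
#'   statistics, `"metagenes"` or `"mixing"` for long weight tables.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.ica_decomposition <- function(x, matrix = c("stats", "metagenes", "mixing"),
                                   ...) {
  matrix <- match.arg(matrix)
  if (matrix == "stats") return(x$component_stats)
  m <- if (matrix == "metagenes") x$metagenes else t(x$mixing)
  tibble::tibble(
    component = rep(rownames(m), each = ncol(m)),
    id = rep(colnames(m), times = nrow(m)),
    value = as.numeric(t(m))
  ) |>
    stats::setNames(c("component", if (matrix == "metagenes") "gene" else "sample",
                      if (matrix == "metagenes") "weight" else "loading"))
}

#' @rdname tidiers
#' @export
glance.ica_decomposition <- function(x, ...) {
  tibble::tibble(
    order = x$order,
    runs = x$runs,
    S_total = mean(x$stabilities),
    min_stability = min(x$stabilities),
    explained_variance_fraction = x$explained_variance_fraction,
    seed = x$seed
  )
}

#' @rdname tidiers
#' @export
tidy.stability_scan <- function(x, ...) profile_points(x)

#' @rdname tidiers
#' @export
glance.stability_scan <- function(x, ...) {
  tibble::tibble(
    n_orders = length(x$profiles),
    min_order = min(x$grid),
    max_order = max(x$grid),
    K = x$K,
    cap_applied = x$cap_applied,
    n_failed = length(x$failed_orders)
  )
}

#' @rdname tidiers
#' @export
tidy.mstd_result <- function(x, ...) {
  tibble::tibble(
    line = c("steep", "flat"),
    slope = c(x$fit$line_steep["slope"], x$fit$line_flat["slope"]),
    intercept = c(x$fit$line_steep["intercept"], x$fit$line_flat["intercept"])
  )
}

#' @rdname tidiers
#' @export
glance.mstd_result <- function(x, ...) {
  tibble::tibble(
    mstd = x$mstd,
    mstd_grid = x$mstd_grid,
    intersection_x = x$intersection_x,
    method = x$method,
    converged = x$fit$converged
  )
}

#' @rdname tidiers
#' @export
tidy.match_graph <- function(x, ...) x$edges

#' @rdname tidiers
#' @export
glance.match_graph <- function(x, ...) {
  tibble::tibble(
    n_components = nrow(x$nodes),
    n_datasets = length(unique(x$nodes$dataset)),
    n_edges = nrow(x$edges),
    threshold = x$threshold
  )
}

#' @rdname tidiers
#' @export
tidy.conservation_report <- function(x, ...) x$components

#' @rdname tidiers
#' @export
glance.conservation_report <- function(x, ...) {
  tidyr::pivot_wider(x$frequencies, names_from = "class",
                     values_from = "frequency")
}
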