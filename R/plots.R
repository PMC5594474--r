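#' Plot overlaid stability profiles
#'
#' One grey line per decomposition order: component stability rank against
#' the stability index. The plot on which the two-line clustering and the
#' MSTD are defined.
#'
#' @param object A `stability_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_scan <- function(object, ...) {
  pts <- profile_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rank, y = .data$stability,
                                    group = .data$order)) +
    ggplot2::geom_line(colour = "grey55", linewidth = 0.3) +
    ggplot2::labs(x = "component stability rank", y = "stability index I_q") +
    ggplot2::theme_minimal()
}

#' Plot an MSTD fit: profiles, fitted lines and the MSTD marker
#'
#' @param object An `mstd_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mstd_result <- function(object, ...) {
  p <- autoplot.stability_scan(object$scan)
  add_line <- function(p, li, colour) {
    if (is.finite(li["slope"])) {
      p + ggplot2::geom_abline(slope = li["slope"],
                               intercept = li["intercept"],
                               colour = colour, linetype = "dashed")
    } else {
      p + ggplot2::geom_vline(xintercept = li["intercept"], colour = colour,
                              linetype = "dashed")
    }
  }
  p <- add_line(p, object$fit$line_steep, "blue")
  p <- add_line(p, object$fit$line_flat, "red")
  p + ggplot2::geom_vline(xintercept = object$mstd, linetype = "dotted") +
    ggplot2::annotate("text", x = object$mstd, y = 1.02,
                      label = paste0("MSTD = ", object$mstd), hjust = -0.1,
                      size = 3) +
    ggplot2::coord_cartesian(
      ylim = c(min(0, min(profile_points(object$scan)$stability)), 1.05))
}

#' Plot average stability against decomposition order
#'
#' The total average stability `S(M)` and the average of the `k` most stable
#' components `S_M(k)` as a function of the order.
#'
#' @param scan A `stability_scan`.
#' @param k Number of top components for the second curve (default 10).
#' @return A ggplot object.
#' @export
plot_average_stability <- function(scan, k = 10L) {
  tbl <- dplyr::bind_rows(lapply(scan$profiles, function(p) {
    tibble::tibble(
      order = p$order,
      statistic = c("S_total", sprintf("S(top %d)", k)),
      value = c(p$S_total,
                average_stability(p$stabilities, min(k, p$order)))
    )
  }))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$order, y = .data$value,
                                    colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "decomposition order M", y = "average stability") +
    ggplot2::theme_minimal()
}

#' Plot a reciprocal-correlation match graph
#'
#' Force-directed layout of the component graph; node colour by dataset,
#' node size by stability where available, edge width by `|r|`.
#'
#' @param object A `match_graph`.
#' @param seed Layout seed (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.match_graph <- function(object, seed = 1L, ...) {
  g <- object$graph
  xy <- with_preserved_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges
  if (nrow(edges) > 0L) {
    ix <- match(edges$from, nodes$name)
    jx <- match(edges$to, nodes$name)
    edges <- dplyr::mutate(edges, x = nodes$x[ix], y = nodes$y[ix],
                           xend = nodes$x[jx], yend = nodes$y[jx])
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0L) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$abs_r),
      colour = "grey60") +
      ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none")
  }
  p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$dataset,
                 size = .data$stability)) +
    ggplot2::scale_size(range = c(1, 4), guide = "none") +
    ggplot2::theme_void()
}
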