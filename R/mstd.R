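#' Default grid of decomposition orders
#'
#' Orders 2 to 50 in steps of 1 and 55 to 100 in steps of 5, the standard
#' scan range for transcriptomic datasets.
#'
#' @return Integer vector of orders.
#' @export
default_order_grid <- function() c(2:50, seq(55L, 100L, by = 5L))

#' Scan decomposition orders and collect stability profiles
#'
#' Runs [decompose_stabilized()] for every order in `grid` and keeps the
#' stability profile (the sorted `I_q` values) of each. Orders exceeding the
#' sample-size cap ([cap_order()]) are reduced to the cap; a failing order is
#' recorded and skipped rather than aborting the scan.
#'
#' @param X An [expression_matrix()].
#' @param grid Integer vector of orders to attempt (default
#'   [default_order_grid()] clipped to the data).
#' @param K Number of fastICA runs per order.
#' @param seed Master seed; each order receives its own sub-seed stream.
#' @param control An [ica_control()].
#' @param cache_dir Optional directory: every per-order decomposition is
#'   persisted there via [write_decomposition()] (prefix `order_<M>`), so
#'   downstream comparison never recomputes ICA.
#' @return A `stability_scan`: `profiles` (list of `stability_profile`
#'   objects with `order`, `stabilities`, `S_total`), `grid` (orders actually
#'   run), `requested_grid`, `cap_applied`, `failed_orders`, `K`, `seed`.
#' @export
scan_orders <- function(X, grid = NULL, K = 100L, seed = 1L,
                        control = ica_control(), cache_dir = NULL) {
  v <- as_expression_values(X)
  cap <- cap_order(max(if (is.null(grid)) 100L else grid), ncol(v))
  requested <- if (is.null(grid)) {
    g <- default_order_grid()
    g[g <= min(cap, min(nrow(v), ncol(v) - 1L))]
  } else {
    as.integer(sort(unique(grid)))
  }
  cap_applied <- any(requested > cap)
  grid_run <- sort(unique(pmin(requested, cap)))
  grid_run <- grid_run[grid_run >= 2L]
  seeds <- derive_seeds(seed, length(grid_run))
  profiles <- list()
  failed <- integer(0)
  for (i in seq_along(grid_run)) {
    M <- grid_run[i]
    dec <- tryCatch(
      decompose_stabilized(X, M, K = K, seed = seeds[i], control = control),
      error = function(e) e
    )
    if (inherits(dec, "error")) {
      warning("order ", M, " failed and was skipped: ", conditionMessage(dec),
              call. = FALSE)
      failed <- c(failed, M)
      next
    }
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write_decomposition(dec, file.path(cache_dir, sprintf("order_%03d", M)))
    }
    profiles[[length(profiles) + 1L]] <- structure(
      list(order = M, stabilities = dec$stabilities,
           S_total = mean(dec$stabilities)),
      class = "stability_profile")
  }
  structure(list(
    profiles = profiles,
    grid = setdiff(grid_run, failed),
    requested_grid = requested,
    cap_applied = cap_applied,
    failed_orders = failed,
    K = K,
    seed = seed
  ), class = "stability_scan")
}

#' @export
print.stability_scan <- function(x, ...) {
  cat(sprintf("<stability_scan> %d orders in [%d, %d], K = %d%s\n",
              length(x$profiles), min(x$grid), max(x$grid), x$K,
              if (x$cap_applied) " (cap applied)" else ""))
  invisible(x)
}

#' Overlay all stability profiles as (rank, stability) points
#'
#' The union over scanned orders of the points (component stability rank,
#' `I_q`) — the grey-line cloud from which the two-line clustering estimates
#' the MSTD.
#'
#' @param scan A `stability_scan`.
#' @return Tibble with columns `order`, `rank` (1-based) and `stability`.
#' @export
profile_points <- function(scan) {
  stopifnot(inherits(scan, "stability_scan"), length(scan$profiles) > 0L)
  dplyr::bind_rows(lapply(scan$profiles, function(p) {
    tibble::tibble(order = p$order, rank = seq_along(p$stabilities),
                   stability = p$stabilities)
  }))
}

# ---- two-line (k-lines, k = 2) clustering ---------------------------------

# Lines are parameterised as centroid + unit direction; slope/intercept are
# derived views (slope Inf for vertical lines).
line_from_dir <- function(center, dir) {
  dir <- unname(dir) / sqrt(sum(dir^2))
  list(center = unname(center), dir = dir)
}

line_slope_intercept <- function(ln) {
  if (abs(ln$dir[1]) < 1e-12) {
    c(slope = Inf, intercept = ln$center[1]) # vertical: x = intercept
  } else {
    s <- ln$dir[2] / ln$dir[1]
    c(slope = s, intercept = ln$center[2] - s * ln$center[1])
  }
}

orth_dist <- function(pts, ln) {
  dx <- pts[, 1] - ln$center[1]
  dy <- pts[, 2] - ln$center[2]
  abs(dx * ln$dir[2] - dy * ln$dir[1])
}

# Total-least-squares line: centroid + leading eigenvector of the 2x2
# scatter. Returns NULL for fewer than 2 distinct points.
tls_line <- function(pts) {
  if (nrow(pts) < 2L) return(NULL)
  ctr <- colMeans(pts)
  d <- sweep(pts, 2L, ctr)
  C <- crossprod(d) / nrow(pts)
  if (sum(abs(C)) < 1e-300) return(NULL)
  e <- eigen(C, symmetric = TRUE)
  line_from_dir(ctr, e$vectors[, 1])
}

steepness <- function(ln) abs(ln$dir[2]) / max(abs(ln$dir[1]), 1e-300)

#' Two-line clustering of a point cloud
#'
#' k-lines clustering with k = 2: alternate between assigning every point to
#' the nearest line by orthogonal distance and refitting each line by total
#' least squares (orthogonal regression) on its points, until assignments
#' stabilize. Initial lines default to a near-vertical and a near-horizontal
#' line through the data bounding box, the analogue of initializing at the
#' ordinate and abscissa axes. Distance ties go to the steeper line. A line
#' that loses all its points is reinitialized through the two points farthest
#' from the other line; repeated collapse aborts.
#'
#' @param points Two-column matrix / data frame (or tibble with `x`, `y`).
#' @param init_lines Optional list of two lines in data units, each
#'   `list(center = c(x, y), dir = c(dx, dy))`.
#' @param max_iter Maximum alternation rounds (default 200).
#' @param on_collinear What to do when all points lie on a single line:
#'   `"error"` (default) or `"flag"` (return a degenerate single-line fit).
#' @details Coordinates are rescaled to the unit bounding box before
#'   clustering, so that orthogonal distances are not dominated by whichever
#'   axis spans the larger numeric range (component ranks run over tens of
#'   units, stabilities over one); fitted lines are reported in the original
#'   data units.
#' @return A `klines_fit`: `line_steep` and `line_flat` as
#'   `(slope, intercept)` in data units, `assignments` (1 = steep, 2 = flat),
#'   `iterations`, `converged`, `objective` (sum of squared orthogonal
#'   distances in normalized coordinates), `degenerate`, plus the internal
#'   parametric `lines` (data units).
#' @export
kline_cluster <- function(points, init_lines = NULL, max_iter = 200L,
                          on_collinear = c("error", "flag")) {
  on_collinear <- match.arg(on_collinear)
  pts0 <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts0) <- "double"
  colnames(pts0) <- c("x", "y")
  if (nrow(pts0) < 4L) stop("need at least 4 points", call. = FALSE)
  # normalize to the unit bounding box
  lo <- apply(pts0, 2L, min)
  rng <- apply(pts0, 2L, function(v) max(v) - min(v))
  rng[rng == 0] <- 1
  normalize <- function(p) sweep(sweep(p, 2L, lo), 2L, rng, "/")
  denorm_line <- function(ln) {
    line_from_dir(lo + ln$center * rng, ln$dir * rng)
  }
  norm_line <- function(ln) {
    line_from_dir((ln$center - lo) / rng, ln$dir / rng)
  }
  pts <- normalize(pts0)
  single <- tls_line(pts)
  if (!is.null(single) && max(orth_dist(pts, single)) < 1e-9) {
    if (on_collinear == "error") {
      stop("all points are collinear; two-line fit is degenerate",
           call. = FALSE)
    }
    si <- line_slope_intercept(denorm_line(single))
    return(structure(list(line_steep = si, line_flat = si,
                          assignments = rep(1L, nrow(pts)), iterations = 0L,
                          converged = TRUE, objective = 0,
                          objective_history = numeric(0), degenerate = TRUE,
                          lines = list(denorm_line(single), denorm_line(single)),
                          points = pts0),
                     class = "klines_fit"))
  }
  if (is.null(init_lines)) {
    # the axes of the normalized plot: the ordinate (left edge) and the
    # abscissa (bottom edge) of the bounding box
    init_lines <- list(
      line_from_dir(c(0, 0.5), c(0, 1)),  # vertical
      line_from_dir(c(0.5, 0), c(1, 0))   # horizontal
    )
  } else {
    init_lines <- lapply(init_lines, norm_line)
  }
  lines <- init_lines
  assign_prev <- rep(0L, nrow(pts))
  iterations <- 0L
  converged <- FALSE
  collapses <- 0L
  objective_history <- numeric(0)
  repeat {
    iterations <- iterations + 1L
    d1 <- orth_dist(pts, lines[[1]])
    d2 <- orth_dist(pts, lines[[2]])
    steeper <- if (steepness(lines[[1]]) >= steepness(lines[[2]])) 1L else 2L
    assign_now <- ifelse(d1 < d2, 1L, ifelse(d2 < d1, 2L, steeper))
    for (j in 1:2) {
      sub <- pts[assign_now == j, , drop = FALSE]
      newline <- tls_line(sub)
      if (is.null(newline)) {
        # collapsed: push the line through the two points farthest from the
        # other line
        other <- lines[[if (j == 1L) 2L else 1L]]
        far <- order(orth_dist(pts, other), decreasing = TRUE)[1:2]
        p1 <- pts[far[1], ]; p2 <- pts[far[2], ]
        if (sum(abs(p1 - p2)) < 1e-300) {
          collapses <- collapses + 1L
          if (collapses > 5L) {
            stop("two-line clustering collapsed repeatedly", call. = FALSE)
          }
          next
        }
        newline <- line_from_dir((p1 + p2) / 2, p2 - p1)
        collapses <- collapses + 1L
        if (collapses > 5L) {
          stop("two-line clustering collapsed repeatedly", call. = FALSE)
        }
      }
      lines[[j]] <- newline
    }
    objective_history[iterations] <- sum(pmin(orth_dist(pts, lines[[1]]),
                                              orth_dist(pts, lines[[2]]))^2)
    if (all(assign_now == assign_prev)) {
      converged <- TRUE
      break
    }
    assign_prev <- assign_now
    if (iterations >= max_iter) break
  }
  objective <- objective_history[iterations]
  lines_data <- lapply(lines, denorm_line)
  steep_first <- steepness(lines_data[[1]]) >= steepness(lines_data[[2]])
  ord <- if (steep_first) 1:2 else 2:1
  assignments <- if (steep_first) assign_prev else 3L - assign_prev
  structure(list(
    line_steep = line_slope_intercept(lines_data[[ord[1]]]),
    line_flat = line_slope_intercept(lines_data[[ord[2]]]),
    assignments = assignments,
    iterations = iterations,
    converged = converged,
    objective = objective,
    objective_history = objective_history,
    degenerate = FALSE,
    lines = lines_data[ord],
    points = pts0
  ), class = "klines_fit")
}

#' @export
print.klines_fit <- function(x, ...) {
  cat("<klines_fit>\n")
  cat(sprintf("  steep line: y = %.4g x + %.4g\n",
              x$line_steep["slope"], x$line_steep["intercept"]))
  cat(sprintf("  flat line:  y = %.4g x + %.4g\n",
              x$line_flat["slope"], x$line_flat["intercept"]))
  cat(sprintf("  objective %.4g after %d iterations (converged: %s)\n",
              x$objective, x$iterations, x$converged))
  invisible(x)
}

# Two-line fit with a small set of deterministic initializations. The
# alternating fit can lock onto a lengthwise split of a thick descending
# band, whose line intersection lies far outside the data and defines no
# dimension, so fits are screened: only converged, non-degenerate fits whose
# intersection falls inside the observed rank range are valid, and the valid
# fit with the smallest objective wins. Falls back to the plain axes-init
# fit when no candidate is valid.
best_kline_fit <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  tls_of <- function(sub) if (nrow(sub) >= 2L) tls_line(sub) else NULL
  lower <- tls_of(pts[y <= stats::median(y), , drop = FALSE])
  inits <- list(
    NULL, # the plot-axes initialization
    if (!is.null(lower)) list(line_from_dir(c(mean(x), max(y)), c(1, 0)),
                              lower),
    list(line_from_dir(c(mean(x[x <= stats::median(x)]), mean(y)), c(1, 0)),
         line_from_dir(c(mean(x[x > stats::median(x)]), mean(y)), c(1, 0)))
  )
  best <- NULL
  fallback <- NULL
  for (init in inits[!vapply(inits, is.null, logical(1)) |
                       seq_along(inits) == 1L]) {
    fit <- tryCatch(kline_cluster(pts, init_lines = init),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(fallback)) fallback <- fit
    xi <- klines_intersection_x(fit)
    valid <- fit$converged && !fit$degenerate && !is.null(xi) &&
      xi >= min(x) && xi <= max(x)
    if (valid && (is.null(best) || fit$objective < best$fit$objective)) {
      best <- list(fit = fit, xint = xi)
    }
  }
  if (!is.null(best)) return(best)
  if (is.null(fallback)) stop("two-line clustering failed", call. = FALSE)
  list(fit = fallback, xint = klines_intersection_x(fallback))
}

# Intersection x of the two fitted parametric lines; NULL when parallel.
klines_intersection_x <- function(fit) {
  l1 <- fit$lines[[1]]; l2 <- fit$lines[[2]]
  cr <- l1$dir[1] * l2$dir[2] - l1$dir[2] * l2$dir[1]
  if (abs(cr) < 1e-9) return(NULL)
  dc <- l2$center - l1$center
  t1 <- (dc[1] * l2$dir[2] - dc[2] * l2$dir[1]) / cr
  (l1$center + t1 * l1$dir)[1]
}

#' Estimate the Maximally Stable Transcriptome Dimension
#'
#' Pools the (rank, `I_q`) points of all scanned stability profiles, fits two
#' lines by [kline_cluster()], and returns the rounded x-coordinate of their
#' intersection, clamped to the scanned order range. If the fitted lines are
#' parallel, a heuristic fallback is used: the smallest scanned order at
#' which more than half of the components have stability below 0.4 (the
#' low-stability band of over-decomposed regimes); the result is then flagged
#' `method = "low_stability_fallback"`.
#'
#' @param scan A `stability_scan` with at least 3 profiles.
#' @param low_stability Stability level defining the fallback band
#'   (default 0.4).
#' @return An `mstd_result`: `mstd` (integer), `mstd_grid` (nearest order at
#'   which a decomposition was actually computed), `intersection_x`, `fit`
#'   (the `klines_fit`), `method`, and the `scan`.
#' @export
estimate_mstd <- function(scan, low_stability = 0.4) {
  stopifnot(inherits(scan, "stability_scan"))
  if (length(scan$profiles) < 3L) {
    stop("need at least 3 stability profiles", call. = FALSE)
  }
  pts <- profile_points(scan)
  sel <- best_kline_fit(as.matrix(pts[, c("rank", "stability")]))
  fit <- sel$fit
  xint <- sel$xint
  lo <- min(scan$grid); hi <- max(scan$grid)
  if (!is.null(xint)) {
    mstd <- min(max(floor(xint + 0.5), lo), hi) # round half-up, clamp
    method <- "two_line_intersection"
  } else {
    frac_low <- vapply(scan$profiles, function(p) {
      mean(p$stabilities < low_stability)
    }, numeric(1))
    hit <- which(frac_low > 0.5)
    mstd <- if (length(hit) > 0L) scan$grid[min(hit)] else hi
    xint <- NA_real_
    method <- "low_stability_fallback"
  }
  grid_near <- scan$grid[which.min(abs(scan$grid - mstd))]
  structure(list(
    mstd = as.integer(mstd),
    mstd_grid = as.integer(grid_near),
    intersection_x = xint,
    fit = fit,
    method = method,
    scan = scan
  ), class = "mstd_result")
}

#' @export
print.mstd_result <- function(x, ...) {
  cat(sprintf("<mstd_result> MSTD = %d (%s)\n", x$mstd, x$method))
  if (is.finite(x$intersection_x)) {
    cat(sprintf("  line intersection at rank %.2f; nearest scanned order %d\n",
                x$intersection_x, x$mstd_grid))
  }
  invisible(x)
}

#' Classical dimension estimates from the PCA spectrum
#'
#' Baselines to compare the MSTD against: the Kaiser rule (number of
#' covariance eigenvalues above the mean eigenvalue) and the broken-stick
#' model (largest `k` such that each of the top `k` variance proportions
#' exceeds its broken-stick expectation
#' `b_j = (1/p) * sum_{i=j}^{p} 1/i`).
#'
#' @param X An [expression_matrix()].
#' @return Tibble with columns `method` (`"kaiser"`, `"broken_stick"`) and
#'   `estimate`.
#' @export
baseline_dimensions <- function(X) {
  v <- as_expression_values(X)
  vc <- v - rowMeans(v)
  vc <- sweep(vc, 2L, colMeans(vc))
  lambda <- eigen(crossprod(vc) / (nrow(v) - 1), symmetric = TRUE,
                  only.values = TRUE)$values
  spectrum_dimensions(pmax(lambda, 0))
}

#' @rdname baseline_dimensions
#' @param eigenvalues Non-negative covariance eigenvalues, any order.
#' @export
spectrum_dimensions <- function(eigenvalues) {
  lambda <- sort(eigenvalues, decreasing = TRUE)
  kaiser <- sum(lambda > mean(lambda))
  p <- length(lambda)
  prop <- lambda / sum(lambda)
  bstick <- rev(cumsum(1 / rev(seq_len(p)))) / p
  ok <- prop > bstick
  broken <- if (!ok[1]) 0L else which.min(c(ok, FALSE)) - 1L
  tibble::tibble(method = c("kaiser", "broken_stick"),
                 estimate = as.integer(c(kaiser, broken)))
}
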