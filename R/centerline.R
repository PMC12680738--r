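# Stream centerline: medial axis of the bank-bounded channel, stationing,
# sinuosity, bend detection and gradient.
#
# The medial axis of a channel bounded by two non-crossing bank polylines
# is the locus of points equidistant from the two banks.  It is computed
# here by seeding matched-arc-length midpoints of the banks and iterating
# each node to the equidistant fixed point (the midpoint of its nearest
# left- and right-bank points), then resampling at uniform arc length.

new_centerline <- function(nodes) {
  nodes <- coords(nodes)
  if (nrow(nodes) < 2L) stop("centerline needs at least two nodes")
  s <- cumulative_s(nodes)
  n <- nrow(nodes)
  tg <- if (n == 2L) rbind(nodes[2L, ] - nodes[1L, ], nodes[2L, ] - nodes[1L, ])
  else rbind(nodes[2L, ] - nodes[1L, ],
             (nodes[3:n, , drop = FALSE] - nodes[1:(n - 2L), , drop = FALSE]) / 2,
             nodes[n, ] - nodes[n - 1L, ])
  tg <- tg / sqrt(rowSums(tg^2))
  structure(list(nodes = nodes, s = s, tangent = tg,
                 straight_dist = sqrt(sum((nodes[n, ] - nodes[1L, ])^2))),
            class = "centerline")
}

#' Build a centerline object from ordered nodes
#'
#' Computes arc-length stationing, unit tangents and the straight
#' inlet-to-outlet distance.  Used directly by tests and by
#' [extract_centerline()].
#'
#' @param nodes ordered n x 2 coordinate matrix.
#' @return an object of class `centerline`.
#' @export
as_centerline <- function(nodes) new_centerline(nodes)

#' Extract the medial-axis centerline of a channel
#'
#' @param banks a [bank_geometry()].
#' @param spacing_m target node spacing (m) of the returned centerline.
#' @param tol convergence tolerance on `|d_left - d_right|`, as a fraction
#'   of the local width.
#' @param max_iter maximum fixed-point iterations.
#' @return a `centerline` whose nodes are equidistant from the two banks;
#'   components `d_left`/`d_right` carry the per-node bank distances.
#' @export
extract_centerline <- function(banks, spacing_m = 1, tol = 1e-8, max_iter = 40L) {
  stopifnot(inherits(banks, "bank_geometry"), spacing_m > 0)
  if (polylines_cross(banks$left_bank, banks$right_bank))
    stop("left and right banks cross each other")
  left <- densify_polyline(banks$left_bank, spacing_m / 2)
  right <- densify_polyline(banks$right_bank, spacing_m / 2)
  Lm <- max(polyline_length(left), polyline_length(right))
  n <- max(8L, ceiling(Lm / spacing_m) + 1L)
  f <- seq(0, 1, length.out = n)
  pts <- (point_along(left, f * polyline_length(left)) +
          point_along(right, f * polyline_length(right))) / 2
  # the channel end edges are not banks, so the equidistant locus is
  # degenerate there; the end nodes stay anchored at the midpoints of the
  # bank endpoints while the interior converges
  p_start <- (left[1L, ] + right[1L, ]) / 2
  p_end <- (left[nrow(left), ] + right[nrow(right), ]) / 2
  refine <- function(pts, iters) {
    n <- nrow(pts)
    for (it in seq_len(iters)) {
      moved <- 0
      for (k in 2:(n - 1L)) {
        a <- nearest_on_polyline(pts[k, ], left)
        b <- nearest_on_polyline(pts[k, ], right)
        p_new <- (a$point + b$point) / 2
        moved <- max(moved, abs(a$dist - b$dist) / max(a$dist + b$dist, 1e-12))
        pts[k, ] <- p_new
      }
      pts[1L, ] <- p_start; pts[n, ] <- p_end
      if (moved < tol) break
    }
    pts
  }
  pts <- refine(pts, max_iter)
  pts <- resample_polyline(pts, spacing_m)
  pts <- refine(pts, 5L)
  dl <- vapply(seq_len(nrow(pts)), function(k) dist_point_polyline(pts[k, ], left), 1)
  dr <- vapply(seq_len(nrow(pts)), function(k) dist_point_polyline(pts[k, ], right), 1)
  if (any(dl <= 0 | dr <= 0))
    stop("degenerate channel: centerline touches a bank")
  ch <- channel_polygon(banks)
  inside <- point_in_polygon(pts, ch)
  if (!all(inside[-c(1L, length(inside))]))
    stop("disconnected channel: centerline leaves the bank polygon")
  # orient inlet -> outlet
  if (sum((pts[1L, ] - banks$inlet)^2) > sum((pts[nrow(pts), ] - banks$inlet)^2)) {
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    tmp <- dl; dl <- rev(dr); dr <- rev(tmp)
  }
  cl <- new_centerline(pts)
  cl$d_left <- dl; cl$d_right <- dr
  cl
}

#' Channel sinuosity
#'
#' Ratio of the meandered centerline length to the straight distance
#' between its endpoints; 1 for a straight channel.
#'
#' @param cl a `centerline`.
#' @return sinuosity ratio (dimensionless, >= 1 up to discretisation).
#' @export
sinuosity <- function(cl) {
  stopifnot(inherits(cl, "centerline"))
  if (cl$straight_dist <= 0)
    stop("coincident centerline endpoints: sinuosity undefined")
  cl$s[length(cl$s)] / cl$straight_dist
}

# Unwrapped heading (radians) at each centerline node.
unwrapped_heading <- function(cl) {
  h <- atan2(cl$tangent[, 2L], cl$tangent[, 1L])
  dh <- diff(h)
  dh <- ((dh + pi) %% (2 * pi)) - pi
  h[1L] + c(0, cumsum(dh))
}

#' Detect channel bends from centerline turning angle
#'
#' The turning angle at a node is the heading change across an arc-length
#' window centred on it; contiguous runs of nodes above the threshold
#' collapse to a single bend at the angle-maximal node.
#'
#' @param cl a `centerline`.
#' @param theta_deg turning-angle threshold (degrees).
#' @param window_m window width (m); coarser polylines are resampled at a
#'   quarter window internally.
#' @return data frame with columns `s`, `x`, `y`, `theta_deg`, one row per
#'   bend (zero rows when none).
#' @export
detect_bends <- function(cl, theta_deg = 30, window_m = 5) {
  stopifnot(inherits(cl, "centerline"), window_m > 0)
  # the window must span several nodes; resample coarse polylines first
  if (window_m < 2 * max(diff(cl$s)))
    cl <- new_centerline(resample_polyline(cl$nodes, window_m / 4))
  s <- cl$s
  h <- unwrapped_heading(cl)
  hfun <- stats::approxfun(s, h, rule = 2)
  turn <- abs(hfun(s + window_m / 2) - hfun(s - window_m / 2)) * 180 / pi
  above <- turn > theta_deg
  out <- data.frame(s = numeric(0), x = numeric(0), y = numeric(0),
                    theta_deg = numeric(0))
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    i <- idx[which.max(turn[idx])]
    out <- rbind(out, data.frame(s = s[i], x = cl$nodes[i, 1L],
                                 y = cl$nodes[i, 2L], theta_deg = turn[i]))
  }
  out
}

#' Channel gradient from endpoint elevations
#'
#' Bed-elevation drop per unit meandered channel length.  A negative
#' slope (downstream end higher than upstream) is returned as-is with a
#' warning so inverted inputs are visible to the caller.
#'
#' @param elev_up,elev_down bed elevations (m) at the upstream and
#'   downstream ends.
#' @param cl a `centerline` providing the channel length.
#' @return slope in m/m.
#' @export
channel_gradient <- function(elev_up, elev_down, cl) {
  stopifnot(inherits(cl, "centerline"))
  L <- cl$s[length(cl$s)]
  if (L <= 0) stop("zero-length centerline")
  slope <- (elev_up - elev_down) / L
  if (slope < 0)
    warning("negative channel gradient: elevations may be inverted")
  slope
}

#' End-to-end and mean-of-segment slopes of a station elevation profile
#'
#' @param s strictly increasing station arc lengths (m).
#' @param elev bed elevations (m) at the stations.
#' @return list with `end_to_end` slope and the length-weighted
#'   `mean_segment` slope (identical by telescoping when weights are the
#'   segment lengths).
#' @export
gradient_profile <- function(s, elev) {
  stopifnot(length(s) == length(elev), length(s) >= 2L,
            !is.unsorted(s, strictly = TRUE))
  ds <- diff(s); de <- -diff(elev)
  list(end_to_end = (elev[1L] - elev[length(elev)]) / (s[length(s)] - s[1L]),
       mean_segment = sum((de / ds) * ds) / sum(ds))
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d nodes, length %.2f m, sinuosity %.3f\n",
              nrow(x$nodes), x$s[length(x$s)],
              x$s[length(x$s)] / max(x$straight_dist, 1e-12)))
  invisible(x)
}
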