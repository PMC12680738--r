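# Shared fixture builders and independent oracles.

# Straight rectangular channel: left bank at y = W, right bank at y = 0.
rect_channel <- function(L = 100, W = 5, top_offset = 2) {
  xs <- seq(0, L, by = 1)
  bank_geometry(left_bank = cbind(xs, W), right_bank = cbind(xs, 0),
                left_bank_top = cbind(xs, W + top_offset),
                right_bank_top = cbind(xs, -top_offset),
                inlet = c(0, W / 2), outlet = c(L, W / 2))
}

# Independent shortest-path oracle: igraph Dijkstra on the same lattice
# contract (8-connected, sqrt(2) diagonals, no corner cutting).
oracle_grid_cost <- function(blocked, start, goal) {
  nx <- nrow(blocked); ny <- ncol(blocked)
  idm <- matrix(seq_len(nx * ny), nx, ny)
  free <- !blocked
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    i_from <- seq_len(nx); i_from <- i_from[i_from + di >= 1L & i_from + di <= nx]
    j_from <- seq_len(ny); j_from <- j_from[j_from + dj >= 1L & j_from + dj <= ny]
    ok <- free[i_from, j_from, drop = FALSE] &
          free[i_from + di, j_from + dj, drop = FALSE]
    if (di != 0L && dj != 0L)
      ok <- ok & free[i_from + di, j_from, drop = FALSE] &
                 free[i_from, j_from + dj, drop = FALSE]
    f <- idm[i_from, j_from, drop = FALSE][ok]
    t <- idm[i_from + di, j_from + dj, drop = FALSE][ok]
    from <- c(from, f); to <- c(to, t)
    w <- c(w, rep(if (di != 0L && dj != 0L) sqrt(2) else 1, length(f)))
  }
  g <- igraph::make_empty_graph(n = nx * ny, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  as.numeric(igraph::distances(g, v = idm[start[1L], start[2L]],
                               to = idm[goal[1L], goal[2L]], mode = "out"))
}

# Exhaustive category cases at every published bin boundary (both gradient
# variants where the metric has two threshold systems).
mmi_bin_cases <- function() {
  eps <- 1e-9
  list(
    list("M2", "M", 10, "excellent"), list("M2", "M", 10 - eps, "good"),
    list("M2", "M", 12, "excellent"),
    list("M2", "M", 5, "good"), list("M2", "M", 5 - eps, "fair"),
    list("M2", "M", 1, "fair"), list("M2", "M", 1 - eps, "poor"),
    list("M3", "M", 0.2 - eps, "excellent"), list("M3", "M", 0.2, "good"),
    list("M3", "M", 0.5 - eps, "good"), list("M3", "M", 0.5, "fair"),
    list("M3", "M", 1 - eps, "fair"), list("M3", "M", 1, "poor"),
    list("M4", "M", 7 - eps, "excellent"), list("M4", "M", 7, "good"),
    list("M4", "M", 15 - eps, "good"), list("M4", "M", 15, "fair"),
    list("M4", "M", 25 - eps, "fair"), list("M4", "M", 25, "poor"),
    list("M4", "M", 26, "poor"),
    list("M5", "H", 7 - eps, "excellent"), list("M5", "H", 7, "good"),
    list("M5", "H", 15, "fair"), list("M5", "H", 25, "poor"),
    list("M5", "M", 3 + eps, "excellent"), list("M5", "M", 3, "good"),
    list("M5", "M", 2 + eps, "good"), list("M5", "M", 2, "fair"),
    list("M5", "M", 1.09, "fair"),
    list("M5", "M", 1 + eps, "fair"), list("M5", "M", 1, "poor"),
    list("M6", "M", 100, "excellent"), list("M6", "M", 100 - 1e-6, "good"),
    list("M6", "M", 75, "good"), list("M6", "M", 75 - eps, "fair"),
    list("M6", "M", 25, "fair"), list("M6", "M", 25 - eps, "poor"),
    list("M6", "M", 0, "poor"),
    list("M7", "H", 70, "excellent"), list("M7", "H", 70 - eps, "good"),
    list("M7", "H", 40, "good"), list("M7", "H", 40 - eps, "fair"),
    list("M7", "H", 20, "fair"), list("M7", "H", 20 - eps, "poor"),
    list("M7", "M", 50, "excellent"), list("M7", "M", 50 - eps, "good"),
    list("M7", "M", 30, "good"), list("M7", "M", 30 - eps, "fair"),
    list("M7", "M", 10, "fair"), list("M7", "M", 10 - eps, "poor"),
    list("M8", "M", 12, "excellent"), list("M8", "M", 12 - eps, "good"),
    list("M8", "M", 7, "good"), list("M8", "M", 7 - eps, "fair"),
    list("M8", "M", 2, "fair"), list("M8", "M", 2 - eps, "poor"),
    list("M9", "M", 50, "excellent"),
    list("M9", "M", 40 + 1e-6, "excellent"), list("M9", "M", 40, "good"),
    list("M9", "M", 60 - 1e-6, "excellent"), list("M9", "M", 60, "good"),
    list("M9", "M", 30 + 1e-6, "good"), list("M9", "M", 30, "fair"),
    list("M9", "M", 70 - 1e-6, "good"), list("M9", "M", 70, "fair"),
    list("M9", "M", 10 + 1e-6, "fair"), list("M9", "M", 10, "poor"),
    list("M9", "M", 90 - 1e-6, "fair"), list("M9", "M", 90, "poor"),
    list("M9", "M", 0, "poor"), list("M9", "M", 100, "poor"),
    list("M9", "M", 10.68, "fair"))
}

# Independent (sampling-based) check that a polyline stays off blocked
# cells.
path_hits_blocked <- function(grid, pts, step = NULL) {
  if (is.null(step)) step <- grid$cell_m / 25
  dense <- densify_polyline_pts(pts, step)
  ij <- cbind(floor((dense[, 1L] - grid$origin[1L]) / grid$cell_m) + 1L,
              floor((dense[, 2L] - grid$origin[2L]) / grid$cell_m) + 1L)
  ij[, 1L] <- pmin(pmax(ij[, 1L], 1L), nrow(grid$blocked))
  ij[, 2L] <- pmin(pmax(ij[, 2L], 1L), ncol(grid$blocked))
  any(grid$blocked[ij])
}

densify_polyline_pts <- function(pts, step) {
  out <- list(pts[1L, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / step))
    f <- seq_len(n) / n
    out[[i + 1L]] <- cbind(a[1L] + f * (b[1L] - a[1L]), a[2L] + f * (b[2L] - a[2L]))
  }
  do.call(rbind, out)
}

route_length <- function(route) {
  wp <- route$waypoints
  sum(sqrt(rowSums((wp[-1L, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2)))
}

# Small meander fixture shared by several test files (cheap to build).
small_meander <- function(...) {
  meander_spec(axis_length = 120, amplitude = 8, wavelength = 80, width = 5,
               pool_reaches = list(c(30, 50)), seed = 7, ...)
}
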