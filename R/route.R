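# Survey flight-route design: obstacle buffering, overlap-driven sweep
# spacing, S-shaped (boustrophedon) coverage, grid-based detouring with
# node simplification, and flight-time budgeting.

#' Buffer obstacles and derive the stream focus corridor
#'
#' Obstacles are dilated by the obstacle clearance buffer (round joins);
#' the stream channel, when present, is dilated by the focus-corridor
#' width and clipped to the flight boundary (clipping requires a convex
#' boundary; non-convex boundaries leave the corridor unclipped with a
#' warning).
#'
#' @param site a [site_plan()].
#' @param cfg a [flight_config()].
#' @return list with `blocked_zones` (list of polygons) and `focus_zone`
#'   (polygon or `NULL`).
#' @export
buffer_features <- function(site, cfg = flight_config()) {
  stopifnot(inherits(site, "site_plan"))
  blocked <- lapply(site$obstacles, buffer_polygon, d = cfg$buffer_obstacle_m)
  focus <- NULL
  if (!is.null(site$stream_channel)) {
    focus <- buffer_polygon(site$stream_channel, cfg$focus_corridor_m)
    if (polygon_is_convex(site$boundary)) {
      clipped <- convex_clip(focus, site$boundary)
      if (nrow(clipped) >= 3L) focus <- clipped
    } else {
      warning("non-convex boundary: focus corridor left unclipped")
    }
  }
  if (length(blocked)) {
    # a site is unflyable when no coarse probe cell stays clear
    bb <- bbox_of(site$boundary)
    gx <- seq(bb["xmin"], bb["xmax"], length.out = 25L)
    gy <- seq(bb["ymin"], bb["ymax"], length.out = 25L)
    probes <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
    probes <- probes[point_in_polygon(probes, site$boundary), , drop = FALSE]
    free <- rep(TRUE, nrow(probes))
    for (bz in blocked) free <- free & !point_in_polygon(probes, bz)
    if (!any(free)) stop("no flyable area: buffered obstacles cover the boundary")
  }
  list(blocked_zones = blocked, focus_zone = focus)
}

#' Sweep-line spacing from altitude, overlap and camera field of view
#'
#' Pinhole model: the cross-track ground footprint at altitude `h` is
#' `2 h tan(FOV/2)`; adjacent lines overlap by `overlap` when spaced at
#' that footprint times `1 - overlap`.
#'
#' @param alt_m flight altitude above ground (m).
#' @param overlap target image side-overlap fraction in `[0, 1)`.
#' @param cam a [camera_model()].
#' @return line spacing in metres.
#' @export
line_spacing <- function(alt_m, overlap, cam = camera_model()) {
  stopifnot(alt_m > 0)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  2 * alt_m * tan(cam$fov_cross_track_deg * pi / 360) * (1 - overlap)
}

new_flight_route <- function(waypoints, segment_class, sweep_lines = list(),
                             alt = NA_real_) {
  waypoints <- coords(waypoints)
  stopifnot(length(segment_class) == max(0L, nrow(waypoints) - 1L))
  d <- sqrt(rowSums((waypoints[-1L, , drop = FALSE] -
                     waypoints[-nrow(waypoints), , drop = FALSE])^2))
  if (any(d < 1e-12)) stop("consecutive waypoints must be distinct")
  structure(list(waypoints = waypoints, segment_class = segment_class,
                 sweep_lines = sweep_lines, alt = alt),
            class = "flight_route")
}

# Widest free span of the horizontal line y = y0 inside the boundary.
row_span <- function(boundary, y0) {
  iv <- line_polygon_intervals(c(0, y0), c(1, 0), boundary)
  if (nrow(iv) == 0L) return(NULL)
  c(min(iv[, 1L]), max(iv[, 2L]))
}

#' Generate an S-shaped (boustrophedon) sweep route
#'
#' Horizontal sweep lines are laid bottom to top at spacing at most
#' `delta_d`, tightened to `delta_d_focus` wherever the band up to the
#' next coarse line would overlap the focus zone, and connected
#' end-to-end in alternating direction.  Sweep lines are classed
#' `survey`, connectors `transit`.  A boundary narrower than the spacing
#' yields a single line through the mid band.
#'
#' @param boundary flight-area polygon.
#' @param delta_d default line spacing (m).
#' @param focus optional focus-zone polygon.
#' @param delta_d_focus spacing over the focus zone (must not exceed
#'   `delta_d`).
#' @param alt altitude tag stored on the route (m).
#' @return a `flight_route`.
#' @export
generate_sweep <- function(boundary, delta_d, focus = NULL,
                           delta_d_focus = delta_d, alt = NA_real_) {
  boundary <- close_ring(boundary)
  if (abs(polygon_area(boundary)) <= 0) stop("degenerate boundary (zero area)")
  stopifnot(delta_d > 0, delta_d_focus > 0)
  if (delta_d_focus > delta_d) stop("delta_d_focus must not exceed delta_d")
  bb <- unname(bbox_of(boundary))          # xmin ymin xmax ymax
  fb <- if (!is.null(focus)) unname(bbox_of(focus))
  extent <- bb[4L] - bb[2L]
  ys <- if (extent <= delta_d) (bb[2L] + bb[4L]) / 2
  else {
    out <- bb[2L]
    y <- bb[2L]
    repeat {
      in_focus_band <- !is.null(fb) && y < fb[4L] && (y + delta_d) > fb[2L]
      y <- y + if (in_focus_band) delta_d_focus else delta_d
      if (y >= bb[4L] - 1e-9) { out <- c(out, bb[4L]); break }
      out <- c(out, y)
    }
    out
  }
  wp <- NULL; cls <- character(0); lines <- list()
  ltr <- TRUE
  for (y in ys) {
    sp <- row_span(boundary, y)
    if (is.null(sp)) {
      # edge-tangent row: nudge inward to get a span
      eps <- 1e-6 * max(1, extent)
      sp <- row_span(boundary, y + if (y <= (bb[2L] + bb[4L]) / 2) eps else -eps)
      if (is.null(sp)) next
    }
    a <- c(sp[1L], y); b <- c(sp[2L], y)
    ends <- if (ltr) rbind(a, b) else rbind(b, a)
    lines[[length(lines) + 1L]] <- ends
    if (is.null(wp)) {
      wp <- ends
      cls <- "survey"
    } else {
      wp <- rbind(wp, ends)
      cls <- c(cls, "transit", "survey")
    }
    ltr <- !ltr
  }
  if (is.null(wp)) stop("no sweep lines could be placed inside the boundary")
  new_flight_route(wp, cls, sweep_lines = lines, alt = alt)
}

#' Rasterize blocked zones onto an occupancy grid
#'
#' Conservative: a cell is blocked when its square intersects any blocked
#' zone (even partially) or its centre falls outside the boundary.
#'
#' @param blocked_zones list of polygons.
#' @param boundary flight-area polygon.
#' @param cell_m cell size (m).
#' @return an `occupancy_grid`: origin (lower-left corner), `cell_m` and a
#'   logical `blocked` matrix indexed `[ix, iy]` along x and y.
#' @export
rasterize_obstacles <- function(blocked_zones, boundary, cell_m = 1) {
  stopifnot(cell_m > 0)
  boundary <- close_ring(boundary)
  bb <- bbox_of(boundary)
  if (cell_m > (bb["xmax"] - bb["xmin"]) || cell_m > (bb["ymax"] - bb["ymin"]))
    stop("cell_m exceeds the boundary extent")
  nx <- ceiling((bb["xmax"] - bb["xmin"]) / cell_m)
  ny <- ceiling((bb["ymax"] - bb["ymin"]) / cell_m)
  origin <- c(bb["xmin"], bb["ymin"])
  cx <- origin[1L] + (seq_len(nx) - 0.5) * cell_m
  cy <- origin[2L] + (seq_len(ny) - 0.5) * cell_m
  centers <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  blocked <- matrix(!point_in_polygon(centers, boundary), nx, ny)
  for (bz in blocked_zones) {
    zb <- bbox_of(bz)
    is_ <- max(1L, floor((zb["xmin"] - origin[1L]) / cell_m)):
           min(nx, ceiling((zb["xmax"] - origin[1L]) / cell_m) + 1L)
    js_ <- max(1L, floor((zb["ymin"] - origin[2L]) / cell_m)):
           min(ny, ceiling((zb["ymax"] - origin[2L]) / cell_m) + 1L)
    is_ <- is_[is_ >= 1L & is_ <= nx]; js_ <- js_[js_ >= 1L & js_ <= ny]
    for (i in is_) for (j in js_) {
      if (blocked[i, j]) next
      if (square_intersects_polygon(cx[i], cy[j], cell_m / 2, bz))
        blocked[i, j] <- TRUE
    }
  }
  structure(list(origin = as.numeric(origin), cell_m = cell_m, blocked = blocked),
            class = "occupancy_grid")
}

cell_of <- function(grid, p) {
  i <- floor((p[1L] - grid$origin[1L]) / grid$cell_m) + 1L
  j <- floor((p[2L] - grid$origin[2L]) / grid$cell_m) + 1L
  c(min(max(i, 1L), nrow(grid$blocked)), min(max(j, 1L), ncol(grid$blocked)))
}

cell_center <- function(grid, ij) {
  grid$origin + (ij - 0.5) * grid$cell_m
}

#' Optimal grid path between two points
#'
#' Dijkstra on the occupancy grid's 8-connected lattice (unit orthogonal,
#' sqrt(2) diagonal cost, no corner cutting past blocked cells),
#' minimising path length first and number of turns second.  Exposed for
#' direct use and verification; [detour_route()] calls the same search.
#'
#' @param grid an `occupancy_grid`.
#' @param from,to points in world coordinates (mapped to their cells).
#' @return list with `points` (cell-centre waypoints, world units), `cost`
#'   (path length in metres) and `turns`; `NULL` when unreachable.
#' @export
grid_shortest_path <- function(grid, from, to) {
  c1 <- cell_of(grid, from); c2 <- cell_of(grid, to)
  res <- .grid_shortest_path(grid$blocked, c1[1L], c1[2L], c2[1L], c2[2L])
  if (length(res) == 0L) return(NULL)   # unreachable
  list(points = t(apply(res$path, 1L, function(ij) cell_center(grid, ij))),
       cost = res$cost * grid$cell_m, turns = res$turns)
}

segment_blocked <- function(grid, p1, p2) {
  .segment_crosses_blocked(grid$blocked, grid$origin[1L], grid$origin[2L],
                           grid$cell_m, p1[1L], p1[2L], p2[1L], p2[2L])
}

#' Detour route edges around blocked cells
#'
#' Every edge crossing a blocked cell is replaced by the optimal grid path
#' (8-connected, diagonal cost sqrt(2), no corner cutting) between the
#' cells containing its endpoints; free edges pass through untouched.
#' Inserted vertices inherit the class of the original edge.
#'
#' @param route a `flight_route`.
#' @param grid an `occupancy_grid`.
#' @return a detoured `flight_route`.
#' @export
detour_route <- function(route, grid) {
  stopifnot(inherits(route, "flight_route"), inherits(grid, "occupancy_grid"))
  wp <- route$waypoints
  out <- wp[1L, , drop = FALSE]; cls <- character(0)
  for (e in seq_len(nrow(wp) - 1L)) {
    p1 <- wp[e, ]; p2 <- wp[e + 1L, ]
    if (!segment_blocked(grid, p1, p2)) {
      out <- rbind(out, p2); cls <- c(cls, route$segment_class[e])
      next
    }
    c1 <- cell_of(grid, p1); c2 <- cell_of(grid, p2)
    if (grid$blocked[c1[1L], c1[2L]] || grid$blocked[c2[1L], c2[2L]])
      stop(sprintf("route endpoint of segment %d lies on a blocked cell", e))
    res <- .grid_shortest_path(grid$blocked, c1[1L], c1[2L], c2[1L], c2[2L])
    if (length(res) == 0L)
      stop(sprintf("no free path exists for blocked segment %d", e))
    pts <- t(apply(res$path, 1L, function(ij) cell_center(grid, ij)))
    pts <- rbind(p1, pts, p2)
    keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
    pts <- pts[keep, , drop = FALSE]
    out <- rbind(out, pts[-1L, , drop = FALSE])
    cls <- c(cls, rep(route$segment_class[e], nrow(pts) - 1L))
  }
  new_flight_route(out, cls, sweep_lines = route$sweep_lines, alt = route$alt)
}

#' Simplify a route by removing redundant nodes
#'
#' Two passes per same-class run of edges: strictly collinear interior
#' nodes are dropped, then a greedy line-of-sight pass removes interior
#' nodes whose bridging segment crosses no blocked cell.  Path length
#' never increases and the result still avoids all blocked cells.
#'
#' @param route a `flight_route` that avoids blocked cells.
#' @param grid an `occupancy_grid`.
#' @return a simplified `flight_route`.
#' @export
simplify_route <- function(route, grid) {
  stopifnot(inherits(route, "flight_route"))
  wp <- route$waypoints; cls <- route$segment_class
  # split into maximal runs of one class
  runs <- rle(cls)
  out <- wp[1L, , drop = FALSE]; ocls <- character(0)
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    n_edges <- runs$lengths[k]
    nodes <- wp[pos:(pos + n_edges), , drop = FALSE]
    nodes <- simplify_nodes(nodes, grid)
    out <- rbind(out, nodes[-1L, , drop = FALSE])
    ocls <- c(ocls, rep(runs$values[k], nrow(nodes) - 1L))
    pos <- pos + n_edges
  }
  new_flight_route(out, ocls, sweep_lines = route$sweep_lines, alt = route$alt)
}

simplify_nodes <- function(nodes, grid) {
  # collinear removal
  if (nrow(nodes) > 2L) {
    keep <- c(TRUE, vapply(2:(nrow(nodes) - 1L), function(i) {
      v1 <- nodes[i, ] - nodes[i - 1L, ]; v2 <- nodes[i + 1L, ] - nodes[i, ]
      abs(v1[1L] * v2[2L] - v1[2L] * v2[1L]) > 1e-9 ||
        sum(v1 * v2) < 0  # keep reversal points
    }, logical(1)), TRUE)
    nodes <- nodes[keep, , drop = FALSE]
  }
  # greedy line-of-sight shortcutting
  i <- 1L; res <- nodes[1L, , drop = FALSE]
  while (i < nrow(nodes)) {
    j <- nrow(nodes)
    while (j > i + 1L && segment_blocked(grid, nodes[i, ], nodes[j, ])) j <- j - 1L
    res <- rbind(res, nodes[j, ])
    i <- j
  }
  res
}

#' Flight time and battery feasibility of a route
#'
#' Survey and transit edges are flown at their class speeds for the given
#' elevation; a fixed liftoff/landing overhead is added.  The route is
#' feasible when the total stays within the usable fraction of the
#' battery.
#'
#' @param route a `flight_route`.
#' @param cfg a [flight_config()].
#' @param elevation `"high"` or `"low"` (selects the speed pair).
#' @return list with `seconds` and `feasible`.
#' @export
flight_time <- function(route, cfg = flight_config(),
                        elevation = c("low", "high")) {
  elevation <- match.arg(elevation)
  stopifnot(inherits(route, "flight_route"))
  wp <- route$waypoints
  spd <- if (elevation == "low")
    c(survey = cfg$speed_survey_low, transit = cfg$speed_transit_low)
  else c(survey = cfg$speed_survey_high, transit = cfg$speed_transit_high)
  secs <- cfg$overhead_s
  if (nrow(wp) > 1L) {
    lens <- sqrt(rowSums((wp[-1L, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2))
    if (!all(route$segment_class %in% names(spd)))
      stop("unknown segment class: ",
           paste(setdiff(route$segment_class, names(spd)), collapse = ", "))
    secs <- secs + sum(lens / spd[route$segment_class])
  }
  list(seconds = secs,
       feasible = secs <= cfg$usable_fraction * cfg$battery_min * 60)
}

#' Plan a complete survey route for a site
#'
#' End-to-end wrapper: buffers features, derives the sweep spacing from
#' altitude, overlap and camera model, lays the S-shaped sweep, rasterizes
#' obstacles, detours blocked edges and simplifies the result.
#'
#' @param site a [site_plan()].
#' @param cfg a [flight_config()].
#' @param cam a [camera_model()].
#' @param elevation `"high"` or `"low"`.
#' @param cell_m occupancy-grid cell size (m).
#' @return list with `route` (a `flight_route`), `grid`, `zones` and
#'   `time` (from [flight_time()]).
#' @export
plan_route <- function(site, cfg = flight_config(), cam = camera_model(),
                       elevation = c("high", "low"), cell_m = 1) {
  elevation <- match.arg(elevation)
  zones <- buffer_features(site, cfg)
  alt <- if (elevation == "high") cfg$alt_high_m else cfg$alt_low_m
  dd <- line_spacing(alt, cfg$overlap_default, cam)
  ddf <- line_spacing(alt, cfg$overlap_focus, cam)
  route <- generate_sweep(site$boundary, dd, zones$focus_zone, ddf, alt = alt)
  grid <- rasterize_obstacles(zones$blocked_zones, site$boundary, cell_m)
  route <- detour_route(route, grid)
  route <- simplify_route(route, grid)
  list(route = route, grid = grid, zones = zones,
       time = flight_time(route, cfg, elevation))
}

#' Export a flight route to GeoJSON and waypoint CSV
#'
#' @param route a `flight_route`.
#' @param geojson_path optional GeoJSON output (LineString with altitude).
#' @param csv_path optional CSV output (x, y, alt_m, speed_mps).
#' @param cfg a [flight_config()] (speeds for the CSV).
#' @param elevation `"high"` or `"low"`.
#' @param crs CRS identifier recorded in the GeoJSON.
#' @export
export_route <- function(route, geojson_path = NULL, csv_path = NULL,
                         cfg = flight_config(), elevation = c("low", "high"),
                         crs = "EPSG:3071") {
  elevation <- match.arg(elevation)
  if (!is.null(geojson_path))
    write_geojson(list(list(type = "LineString", coords = route$waypoints,
                            properties = list(kind = "flight_route",
                                              alt_m = route$alt))),
                  geojson_path, crs)
  if (!is.null(csv_path)) {
    spd <- if (elevation == "low")
      c(survey = cfg$speed_survey_low, transit = cfg$speed_transit_low)
    else c(survey = cfg$speed_survey_high, transit = cfg$speed_transit_high)
    v <- c(spd[route$segment_class], spd[["transit"]])
    utils::write.csv(data.frame(x = route$waypoints[, 1L],
                                y = route$waypoints[, 2L],
                                alt_m = route$alt, speed_mps = as.numeric(v)),
                     csv_path, row.names = FALSE)
  }
  invisible(route)
}

#' @export
print.flight_route <- function(x, ...) {
  lens <- if (nrow(x$waypoints) > 1L)
    sqrt(rowSums((x$waypoints[-1L, , drop = FALSE] -
                  x$waypoints[-nrow(x$waypoints), , drop = FALSE])^2))
  else numeric(0)
  cat(sprintf("<flight_route> %d waypoints, survey %.0f m, transit %.0f m\n",
              nrow(x$waypoints), sum(lens[x$segment_class == "survey"]),
              sum(lens[x$segment_class == "transit"])))
  invisible(x)
}
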