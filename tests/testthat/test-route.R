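# Flight-route planning: buffering, spacing, sweep, rasterisation,
# detouring, simplification, timing.

test_that("obstacle buffering matches the dilation closed form", {
  boundary <- rbind(c(-20, -20), c(20, -20), c(20, 20), c(-20, 20))
  tree <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
  site <- site_plan(boundary, list(tree), "tree")
  z <- buffer_features(site, flight_config(buffer_obstacle_m = 5))
  expect_length(z$blocked_zones, 1L)
  bz <- z$blocked_zones[[1L]]
  expect_equal(streamhab:::polygon_area(bz), 1 + 4 * 5 + pi * 25, tolerance = 0.2)
  expect_true(all(streamhab:::point_in_polygon(tree, bz)))
  # no obstacles: nothing blocked
  z0 <- buffer_features(site_plan(boundary))
  expect_length(z0$blocked_zones, 0L)
})

test_that("the focus corridor is the stream dilated by the corridor width", {
  boundary <- rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40))
  stream <- rbind(c(5, 19), c(55, 19), c(55, 21), c(5, 21))  # 2 m wide
  site <- site_plan(boundary, stream_channel = stream)
  z <- buffer_features(site, flight_config(focus_corridor_m = 10))
  iv <- streamhab:::line_polygon_intervals(c(30, 0), c(0, 1), z$focus_zone)
  expect_equal(sum(iv[, 2L] - iv[, 1L]), 22, tolerance = 0.05)
})

test_that("an unflyable site is refused", {
  boundary <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  blocker <- rbind(c(-2, -2), c(12, -2), c(12, 12), c(-2, 12))
  site <- site_plan(boundary, list(blocker), "building")
  expect_error(buffer_features(site), "no flyable area")
})

test_that("line spacing follows the pinhole footprint formula", {
  cam60 <- camera_model(fov_cross_track_deg = 60)
  expect_equal(line_spacing(30, 0.75, cam60), 2 * 30 * tan(pi / 6) * 0.25,
               tolerance = 1e-12)
  expect_equal(line_spacing(30, 0.75, cam60), 8.660, tolerance = 1e-3)
  expect_equal(line_spacing(5, 0.90, cam60), 0.577, tolerance = 1e-3)
  expect_error(line_spacing(30, 1, cam60), "overlap")
  # strictly decreasing in overlap, increasing in altitude
  ovl <- seq(0, 0.95, by = 0.05)
  d <- vapply(ovl, function(o) line_spacing(30, o, cam60), 1)
  expect_true(all(diff(d) < 0))
  alt <- seq(5, 60, by = 5)
  d2 <- vapply(alt, function(a) line_spacing(a, 0.75, cam60), 1)
  expect_true(all(diff(d2) > 0))
  # overlap -> 1 limit drives the spacing to zero
  expect_lt(line_spacing(30, 1 - 1e-9, cam60), 1e-6)
})

test_that("a square site gets the expected S-shaped sweep", {
  boundary <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  route <- generate_sweep(boundary, delta_d = 25)
  expect_length(route$sweep_lines, 5L)
  wp <- route$waypoints
  lens <- sqrt(rowSums((wp[-1L, ] - wp[-nrow(wp), ])^2))
  expect_equal(sum(lens[route$segment_class == "survey"]), 500, tolerance = 1e-6)
  expect_equal(sum(lens[route$segment_class == "transit"]), 100, tolerance = 1e-6)
  # alternating direction
  dirs <- vapply(route$sweep_lines, function(l) sign(l[2, 1] - l[1, 1]), 1)
  expect_true(all(dirs == rep(c(1, -1), length.out = length(dirs))))
  # narrow boundary: single line through the mid band
  narrow <- rbind(c(0, 0), c(100, 0), c(100, 10), c(0, 10))
  r2 <- generate_sweep(narrow, delta_d = 25)
  expect_length(r2$sweep_lines, 1L)
  expect_equal(r2$waypoints[1, 2], 5)
  expect_error(generate_sweep(rbind(c(0, 0), c(1, 0), c(2, 0)), 5), "degenerate")
})

test_that("focus zones tighten line spacing only across the strip", {
  boundary <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  focus <- rbind(c(0, 45), c(100, 45), c(100, 55), c(0, 55))
  base <- generate_sweep(boundary, delta_d = 20)
  fine <- generate_sweep(boundary, delta_d = 20, focus = focus, delta_d_focus = 10)
  ys_base <- vapply(base$sweep_lines, function(l) l[1, 2], 1)
  ys_fine <- vapply(fine$sweep_lines, function(l) l[1, 2], 1)
  expect_gt(length(ys_fine), length(ys_base))
  gaps <- diff(sort(ys_fine))
  # every gap stays within the coarse spacing; gaps spanning the strip are fine
  expect_true(all(gaps <= 20 + 1e-9))
  in_strip <- sort(ys_fine)[-1] > 45 & sort(ys_fine)[-1] < 55
  expect_true(all(gaps[in_strip] <= 10 + 1e-9))
  # far below the strip the coarse spacing is kept
  expect_true(all(gaps[sort(ys_fine)[-length(ys_fine)] < 20] >= 20 - 1e-9))
})

test_that("rasterisation is conservative and bounded", {
  boundary <- rbind(c(0, 0), c(30, 0), c(30, 30), c(0, 30))
  grid0 <- rasterize_obstacles(list(), boundary, cell_m = 1)
  expect_false(any(grid0$blocked))
  zone <- rbind(c(10.2, 10.2), c(15.2, 10.2), c(15.2, 15.2), c(10.2, 15.2))
  grid <- rasterize_obstacles(list(zone), boundary, cell_m = 1)
  nb <- sum(grid$blocked)
  expect_gte(nb, 25)
  expect_lte(nb, 49)
  # obstacle fully outside the boundary leaves the interior free
  far <- rbind(c(50, 50), c(55, 50), c(55, 55), c(50, 55))
  grid2 <- rasterize_obstacles(list(far), boundary, cell_m = 1)
  expect_false(any(grid2$blocked))
  expect_error(rasterize_obstacles(list(), boundary, cell_m = 40), "extent")
})

test_that("detouring matches the Dijkstra oracle through a wall gap", {
  boundary <- rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20))
  # wall across the middle with one gap
  wall1 <- rbind(c(9.5, 0), c(10.5, 0), c(10.5, 8), c(9.5, 8))
  wall2 <- rbind(c(9.5, 11), c(10.5, 11), c(10.5, 20), c(9.5, 20))
  grid <- rasterize_obstacles(list(wall1, wall2), boundary, cell_m = 1)
  route <- streamhab:::new_flight_route(rbind(c(2.5, 4.5), c(17.5, 4.5)), "survey")
  det <- detour_route(route, grid)
  expect_gt(nrow(det$waypoints), 2L)
  expect_false(path_hits_blocked(grid, det$waypoints))
  res <- grid_shortest_path(grid, c(2.5, 4.5), c(17.5, 4.5))
  oc <- oracle_grid_cost(grid$blocked,
                         streamhab:::cell_of(grid, c(2.5, 4.5)),
                         streamhab:::cell_of(grid, c(17.5, 4.5)))
  expect_equal(res$cost, oc, tolerance = 1e-9)
  # free grid: identity
  grid0 <- rasterize_obstacles(list(), boundary, cell_m = 1)
  det0 <- detour_route(route, grid0)
  expect_equal(det0$waypoints, route$waypoints)
  # sealed goal: error
  box <- rbind(c(14, 1), c(20, 1), c(20, 8), c(14, 8))
  gridb <- rasterize_obstacles(list(box), boundary, cell_m = 1)
  expect_error(detour_route(route, gridb), "blocked cell|no free path")
})

test_that("grid search equals the oracle on random grids", {
  set.seed(42)
  n_trials <- 0L
  while (n_trials < 25L) {
    nx <- sample(8:30, 1); ny <- sample(8:30, 1)
    blocked <- matrix(stats::runif(nx * ny) < 0.25, nx, ny)
    free <- which(!blocked, arr.ind = TRUE)
    if (nrow(free) < 2L) next
    se <- free[sample(nrow(free), 2L), , drop = FALSE]
    grid <- structure(list(origin = c(0, 0), cell_m = 1, blocked = blocked),
                      class = "occupancy_grid")
    oc <- oracle_grid_cost(blocked, se[1L, ], se[2L, ])
    res <- grid_shortest_path(grid, se[1L, ] - 0.5, se[2L, ] - 0.5)
    if (is.null(res)) {
      expect_true(is.infinite(oc))
    } else {
      expect_equal(res$cost, oc, tolerance = 1e-9)
      expect_false(path_hits_blocked(grid, res$points))
    }
    n_trials <- n_trials + 1L
  }
})

test_that("simplification removes collinear and shortcut nodes", {
  boundary <- rbind(c(0, 0), c(10, 0), c(10, 8), c(0, 8))
  grid0 <- rasterize_obstacles(list(), boundary, cell_m = 1)
  # 5 collinear nodes collapse to 2
  col5 <- streamhab:::new_flight_route(cbind(c(1, 2, 3, 4, 5), 1), rep("transit", 4))
  s1 <- simplify_route(col5, grid0)
  expect_equal(nrow(s1$waypoints), 2L)
  # staircase around nothing collapses to a single segment
  stair <- streamhab:::new_flight_route(
    rbind(c(0.5, 0.5), c(1.5, 0.5), c(1.5, 1.5), c(2.5, 1.5), c(2.5, 2.5),
          c(3.5, 2.5), c(3.5, 3.5)), rep("transit", 6))
  s2 <- simplify_route(stair, grid0)
  expect_equal(nrow(s2$waypoints), 2L)
  expect_lte(route_length(s2), route_length(stair))
})

test_that("the ten-node detour pattern simplifies to six nodes", {
  # wall (x in [5,6], y in [0,4]), canopy (x in [2,3], y in [2,3]) and
  # pillar (x in [7,8], y in [1,4]) force the classic pattern: a straight
  # run N1..N5, a climb N5-N6, an unnecessary turning node N7 over the
  # wall, and a descent N8-N9-N10.
  blocked <- matrix(FALSE, 10, 8)
  blocked[6, 1:4] <- TRUE   # wall
  blocked[3, 3] <- TRUE     # canopy
  blocked[8, 2:4] <- TRUE   # pillar
  grid <- structure(list(origin = c(0, 0), cell_m = 1, blocked = blocked),
                    class = "occupancy_grid")
  nodes <- rbind(N1 = c(0.5, 0.5), N2 = c(1.5, 0.5), N3 = c(2.5, 0.5),
                 N4 = c(3.5, 0.5), N5 = c(4.5, 0.5), N6 = c(4.5, 4.5),
                 N7 = c(5.5, 5.5), N8 = c(6.5, 4.5), N9 = c(6.5, 0.5),
                 N10 = c(9.5, 0.5))
  route <- streamhab:::new_flight_route(nodes, rep("transit", 9))
  expect_false(path_hits_blocked(grid, nodes))
  simp <- simplify_route(route, grid)
  expect_equal(nrow(simp$waypoints), 6L)
  expect_equal(unname(simp$waypoints),
               unname(nodes[c("N1", "N5", "N6", "N8", "N9", "N10"), ]))
  expect_false(path_hits_blocked(grid, simp$waypoints))
  expect_lte(route_length(simp), route_length(route))
})

test_that("flight time sums class speeds plus overhead and gates on battery", {
  cfg <- flight_config()
  r <- streamhab:::new_flight_route(rbind(c(0, 0), c(100, 0), c(100, 60)),
                                    c("survey", "transit"))
  ft <- flight_time(r, cfg, "low")
  expect_equal(ft$seconds, 100 / 1 + 60 / 2 + 30)
  expect_true(ft$feasible)
  # 1000 m of survey at 1 m/s busts the 900 s usable budget
  long <- streamhab:::new_flight_route(rbind(c(0, 0), c(1000, 0)), "survey")
  ft2 <- flight_time(long, cfg, "low")
  expect_equal(ft2$seconds, 1030)
  expect_false(ft2$feasible)
  expect_equal(0.75 * 20 * 60, 900)
  # single waypoint: overhead only
  one <- structure(list(waypoints = rbind(c(0, 0)), segment_class = character(0),
                        sweep_lines = list(), alt = 5), class = "flight_route")
  expect_equal(flight_time(one, cfg, "low")$seconds, 30)
  # unknown class
  bad <- streamhab:::new_flight_route(rbind(c(0, 0), c(1, 0)), "hover")
  expect_error(flight_time(bad, cfg, "low"), "unknown segment class")
  # additivity over concatenation (minus one overhead)
  r2 <- streamhab:::new_flight_route(rbind(c(100, 60), c(160, 60)), "survey")
  joint <- streamhab:::new_flight_route(rbind(c(0, 0), c(100, 0), c(100, 60), c(160, 60)),
                                        c("survey", "transit", "survey"))
  expect_equal(flight_time(joint, cfg, "low")$seconds,
               flight_time(r, cfg, "low")$seconds +
                 flight_time(r2, cfg, "low")$seconds - 30)
})

test_that("planned routes keep the buffer clearance to raw obstacles", {
  boundary <- rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40))
  obstacle <- rbind(c(25, 15), c(35, 15), c(35, 25), c(25, 25))
  site <- site_plan(boundary, list(obstacle), "building")
  plan <- plan_route(site, flight_config(), camera_model(fov_cross_track_deg = 60),
                     elevation = "high", cell_m = 1)
  wp <- plan$route$waypoints
  dense <- densify_polyline_pts(wp, 0.1)
  dmin <- min(vapply(seq_len(nrow(dense)), function(i)
    streamhab:::dist_point_polygon(dense[i, ], obstacle), 1))
  expect_gte(dmin, 5 - 0.02)
  expect_false(path_hits_blocked(plan$grid, wp))
  expect_true(plan$time$feasible)
})
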