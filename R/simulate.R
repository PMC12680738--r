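# Parametric meandering-channel generator with analytically known ground
# truth.  The centerline is a sine-generated curve y = a sin(2*pi*x/lambda);
# banks and habitat layers are normal offsets of it, so width, depth,
# buffer/erosion/cover profiles, pool reaches, island geometry, sinuosity
# (by quadrature) and bend stations are all known exactly at generation
# time.

eval_profile <- function(p, s) {
  if (is.function(p)) return(as.numeric(p(s)))
  if (is.numeric(p) && length(p) == 1L) return(rep(p, length(s)))
  tb <- as.data.frame(p)
  if (ncol(tb) < 2L) stop("profile table needs columns (s, value)")
  stats::approx(tb[[1L]], tb[[2L]], xout = s, rule = 2)$y
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic meandering stream site
#'
#' Defines a sine-generated channel `y = amplitude * sin(2*pi*x/wavelength)`
#' over `x` in `[0, axis_length]`, with arbitrary along-stream profiles for
#' width, depth and the per-side habitat layers.  Profiles may be a single
#' number, a function of arc length `s`, or a two-column `(s, value)`
#' table (linearly interpolated).
#'
#' @param axis_length straight valley-axis length (m).
#' @param amplitude,wavelength meander amplitude and wavelength (m).
#' @param width wetted-width profile W(s) (m).
#' @param depth_base base water depth outside pools (m).
#' @param depth_pool_extra additional depth inside pool reaches (m).
#' @param pool_reaches list of `c(s_start, s_end)` pool intervals (m).
#' @param buffer_left,buffer_right riparian buffer width profiles (m).
#' @param erosion_left,erosion_right eroded bank width profiles (m).
#' @param cover_left,cover_right in-stream cover width profiles (m).
#' @param debris_left,debris_right lists of `c(s_start, s_end)` reaches with
#'   woody debris along each bank.
#' @param bank_top_offset distance from bank to bank top (m).
#' @param islands list of `list(s_center=, length=, width=)` in-channel
#'   islands.
#' @param water_surface constant water-surface elevation (m).
#' @param white_base white-water pixel fraction outside pools.
#' @param step along-axis sampling step (m) of the generated geometry.
#' @param bed_spacing spacing (m) of the riverbed elevation samples.
#' @param n_obstacles number of random obstacles placed around the site.
#' @param seed integer seed controlling all randomness.
#' @return an object of class `meander_spec`.
#' @export
meander_spec <- function(axis_length = 200, amplitude = 10, wavelength = 100,
                         width = 5, depth_base = 0.4, depth_pool_extra = 0.8,
                         pool_reaches = list(),
                         buffer_left = 12, buffer_right = 12,
                         erosion_left = 0.1, erosion_right = 0.1,
                         cover_left = 0.3, cover_right = 0.3,
                         debris_left = list(), debris_right = list(),
                         bank_top_offset = 2, islands = list(),
                         water_surface = 263, white_base = 0,
                         step = 0.5, bed_spacing = 1, n_obstacles = 0L,
                         seed = 1L) {
  stopifnot(axis_length > 0, amplitude >= 0, wavelength > 0, step > 0)
  for (pr in pool_reaches) stopifnot(length(pr) == 2L, pr[1L] < pr[2L])
  if (length(pool_reaches) > 1L) {
    m <- do.call(rbind, pool_reaches)
    m <- m[order(m[, 1L]), , drop = FALSE]
    if (any(m[-1L, 1L] < m[-nrow(m), 2L])) stop("pool reaches overlap")
  }
  structure(as.list(environment())[names(formals(meander_spec))],
            class = "meander_spec")
}

in_reaches <- function(s, reaches) {
  hit <- rep(FALSE, length(s))
  for (r in reaches) hit <- hit | (s >= r[1L] & s <= r[2L])
  hit
}

# Offset the generated centerline along its analytic normal.
offset_center <- function(xy, normal, d) cbind(xy[, 1L] + d * normal[, 1L],
                                               xy[, 2L] + d * normal[, 2L])

# Strip polygon between two lateral offsets over a contiguous index run.
strip_polygon <- function(xy, normal, off_inner, off_outer, idx) {
  a <- offset_center(xy[idx, , drop = FALSE], normal[idx, , drop = FALSE], off_inner[idx])
  b <- offset_center(xy[idx, , drop = FALSE], normal[idx, , drop = FALSE], off_outer[idx])
  close_ring(rbind(a, b[rev(seq_len(nrow(b))), , drop = FALSE]))
}

# Split indices where `width > 0` into maximal runs and build one strip per
# run.  `sign` is +1 for the left side of the tangent, -1 for the right.
side_strips <- function(xy, normal, halfw, widths, sign, from = halfw) {
  polys <- list()
  pos <- widths > 1e-9
  if (!any(pos)) return(polys)
  r <- rle(pos)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 2L) next
    polys[[length(polys) + 1L]] <-
      strip_polygon(xy, normal, sign * from, sign * (from + widths), idx)
  }
  polys
}

#' Generate a synthetic stream site from a meander specification
#'
#' @param spec a [meander_spec()].
#' @return list of class `stream_fixture` with components `site`
#'   ([site_plan()]), `banks` ([bank_geometry()]), `layers`
#'   ([layer_set()]), `truth` (ground-truth list) and `spec`.
#' @export
generate_site <- function(spec) {
  stopifnot(inherits(spec, "meander_spec"))
  k <- 2 * pi / spec$wavelength
  tt <- seq(0, spec$axis_length, by = spec$step)
  if (tt[length(tt)] < spec$axis_length) tt <- c(tt, spec$axis_length)
  xy <- cbind(tt, spec$amplitude * sin(k * tt))
  dy <- spec$amplitude * k * cos(k * tt)
  nrm <- 1 / sqrt(1 + dy^2)
  tangent <- cbind(nrm, dy * nrm)
  normal <- cbind(-tangent[, 2L], tangent[, 1L])   # left of flow
  s <- cumulative_s(xy)
  Wv <- eval_profile(spec$width, s)
  kappa_max <- spec$amplitude * k^2
  if (kappa_max > 0 && max(Wv) / 2 >= 1 / kappa_max)
    stop("meander too tight: banks would self-intersect ",
         "(half-width exceeds minimum curvature radius)")
  halfw <- Wv / 2
  left <- offset_center(xy, normal, halfw)
  right <- offset_center(xy, normal, -halfw)
  left_top <- offset_center(xy, normal, halfw + spec$bank_top_offset)
  right_top <- offset_center(xy, normal, -(halfw + spec$bank_top_offset))

  Bl <- eval_profile(spec$buffer_left, s);  Br <- eval_profile(spec$buffer_right, s)
  El <- eval_profile(spec$erosion_left, s); Er <- eval_profile(spec$erosion_right, s)
  Fl <- eval_profile(spec$cover_left, s);   Fr <- eval_profile(spec$cover_right, s)

  layers <- layer_set(
    erosion = sided(side_strips(xy, normal, halfw, El, +1),
                    side_strips(xy, normal, halfw, Er, -1)),
    veg_buffer = sided(side_strips(xy, normal, halfw, Bl, +1),
                       side_strips(xy, normal, halfw, Br, -1)),
    instream_cover = sided(
      side_strips(xy, normal, halfw, Fl, +1, from = halfw - Fl),
      side_strips(xy, normal, halfw, Fr, -1, from = halfw - Fr)),
    woody_debris = sided(
      side_strips(xy, normal, halfw, ifelse(in_reaches(s, spec$debris_left), 1, 0), +1),
      side_strips(xy, normal, halfw, ifelse(in_reaches(s, spec$debris_right), 1, 0), -1)),
    bed_points = NULL, water_surface = spec$water_surface)

  Dv <- spec$depth_base + spec$depth_pool_extra * in_reaches(s, spec$pool_reaches)
  bed_idx <- seq(1L, length(s), by = max(1L, round(spec$bed_spacing / spec$step)))
  layers$bed_points <- data.frame(x = xy[bed_idx, 1L], y = xy[bed_idx, 2L],
                                  elev = spec$water_surface - Dv[bed_idx])
  wf <- rep(spec$white_base, length(s))
  wf[in_reaches(s, spec$pool_reaches)] <- 0
  layers$white_fraction <- data.frame(s = s, frac = wf)

  islands <- list()
  wet <- rep(1, length(s))
  Wwet <- Wv
  for (isl in spec$islands) {
    idx <- which(s >= isl$s_center - isl$length / 2 & s <= isl$s_center + isl$length / 2)
    if (length(idx) < 2L) next
    iw <- rep(isl$width, length(s))
    islands[[length(islands) + 1L]] <-
      strip_polygon(xy, normal, rep(-isl$width / 2, length(s)), iw / 2, idx)
    wet[idx] <- 1 - isl$width / Wv[idx]
    Wwet[idx] <- Wv[idx] - isl$width
  }

  banks <- bank_geometry(left_bank = left, right_bank = right,
                         left_bank_top = left_top, right_bank_top = right_top,
                         islands = islands,
                         inlet = xy[1L, ], outlet = xy[nrow(xy), ])

  bb <- bbox_of(rbind(left_top, right_top))
  margin <- 30
  boundary <- rbind(c(bb["xmin"] - margin, bb["ymin"] - margin),
                    c(bb["xmax"] + margin, bb["ymin"] - margin),
                    c(bb["xmax"] + margin, bb["ymax"] + margin),
                    c(bb["xmin"] - margin, bb["ymax"] + margin))
  site <- if (spec$n_obstacles > 0L) {
    fld <- generate_obstacle_field(extent = boundary, n_obstacles = spec$n_obstacles,
                                   seed = spec$seed,
                                   keep_clear = channel_polygon(banks))
    site_plan(boundary, fld$obstacles, fld$obstacle_kind,
              stream_channel = channel_polygon(banks))
  } else
    site_plan(boundary, stream_channel = channel_polygon(banks))

  # analytic ground truth
  arc_el <- function(t) sqrt(1 + (spec$amplitude * k * cos(k * t))^2)
  L0 <- stats::integrate(arc_el, 0, spec$axis_length, rel.tol = 1e-10,
                         subdivisions = 1000L)$value
  straight <- sqrt(spec$axis_length^2 +
                   (spec$amplitude * (sin(k * spec$axis_length) - 0))^2)
  heading <- atan(dy)
  hfun <- stats::approxfun(s, heading, rule = 2)
  truth <- list(
    centerline = xy, s = s, L0 = L0, sinuosity = L0 / straight,
    straight_dist = straight,
    profiles = data.frame(s = s, W = Wv, W_wetted = Wwet, BT = Wv + 2 * spec$bank_top_offset,
                          D = Dv, B_left = Bl, B_right = Br,
                          E_left = El, E_right = Er, F_left = Fl, F_right = Fr,
                          wet_fraction = wet, white_fraction = wf),
    pool_reaches = spec$pool_reaches,
    pool_fraction = sum(vapply(spec$pool_reaches,
                               function(r) diff(truth_clamp(r, L0)), 1)) / L0,
    bend_stations = truth_bends(s, hfun, theta_deg = 30, window_m = 5),
    debris_cover = list(
      left = sum(vapply(spec$debris_left, function(r) diff(truth_clamp(r, L0)), 1)) / L0,
      right = sum(vapply(spec$debris_right, function(r) diff(truth_clamp(r, L0)), 1)) / L0))
  structure(list(site = site, banks = banks, layers = layers,
                 truth = truth, spec = spec),
            class = "stream_fixture")
}

truth_clamp <- function(r, L0) c(max(r[1L], 0), min(r[2L], L0))

# Bend stations of the analytic centerline: windowed heading change above
# threshold, one station per contiguous run at the angle-maximal point.
truth_bends <- function(s, hfun, theta_deg, window_m) {
  grid <- seq(window_m / 2, max(s) - window_m / 2, by = 0.1)
  if (length(grid) < 2L) return(numeric(0))
  turn <- abs(hfun(grid + window_m / 2) - hfun(grid - window_m / 2)) * 180 / pi
  above <- turn > theta_deg
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  vapply(which(r$values), function(kk) {
    idx <- starts[kk]:ends[kk]
    grid[idx[which.max(turn[idx])]]
  }, 1)
}

#' Generate a random obstacle field
#'
#' Places non-overlapping rectangular and circular obstacles, tagged
#' alternately `tree` / `building`, inside a boundary.  Placement is
#' seed-deterministic; an error is raised when the requested count cannot
#' be placed disjointly after bounded retries.
#'
#' @param extent either a boundary polygon or `c(width, height)` of a
#'   rectangle anchored at the origin.
#' @param n_obstacles number of obstacles.
#' @param seed integer seed.
#' @param size_range obstacle half-size range (m).
#' @param keep_clear optional polygon obstacles must not intersect.
#' @param max_tries placement attempts per obstacle.
#' @return a [site_plan()].
#' @export
generate_obstacle_field <- function(extent, n_obstacles, seed = 1L,
                                    size_range = c(2, 6), keep_clear = NULL,
                                    max_tries = 200L) {
  stopifnot(n_obstacles >= 0)
  boundary <- if (is.matrix(extent) || is.data.frame(extent)) close_ring(extent)
  else rbind(c(0, 0), c(extent[1L], 0), c(extent[1L], extent[2L]), c(0, extent[2L]))
  bb <- bbox_of(boundary)
  obstacles <- list(); kinds <- character()
  with_seed(seed, {
    for (i in seq_len(n_obstacles)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, bb["xmin"], bb["xmax"])
        cy <- stats::runif(1, bb["ymin"], bb["ymax"])
        h <- stats::runif(1, size_range[1L], size_range[2L])
        cand <- if (i %% 2L == 1L) {
          ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
          cbind(cx + h * cos(ang), cy + h * sin(ang))
        } else
          rbind(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h), c(cx - h, cy + h))
        if (!all(point_in_polygon(cand, boundary))) next
        if (!is.null(keep_clear) && polygons_touch(cand, keep_clear)) next
        ok <- TRUE
        for (ob in obstacles) if (polygons_touch(cand, ob)) { ok <- FALSE; break }
        if (ok) {
          obstacles[[length(obstacles) + 1L]] <- cand
          kinds <- c(kinds, if (i %% 2L == 1L) "tree" else "building")
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n_obstacles, " disjoint obstacles after ",
             max_tries, " tries each")
    }
  })
  site_plan(boundary, obstacles, kinds)
}

polygons_touch <- function(a, b) {
  a <- close_ring(a); b <- close_ring(b)
  if (any(point_in_polygon(a, b)) || any(point_in_polygon(b, a))) return(TRUE)
  polylines_cross(rbind(a, a[1L, , drop = FALSE]), rbind(b, b[1L, , drop = FALSE]))
}

#' Insert a localized impairment into a generated fixture
#'
#' Rebuilds the fixture with one habitat layer degraded over an arc-length
#' window: `M2` removes the riparian buffer, `M3` widens erosion, `M7`
#' removes woody debris and `M8` removes in-stream cover.  Ground truth is
#' regenerated alongside, so expected categories stay consistent.
#'
#' @param fixture a `stream_fixture` from [generate_site()].
#' @param window `c(s_start, s_end)` arc-length window (m).
#' @param which metric code: `"M2"`, `"M3"`, `"M7"` or `"M8"`.
#' @param side `"left"` or `"right"`.
#' @param value erosion width (m) installed in the window for `"M3"`.
#' @return a new `stream_fixture`.
#' @export
degrade <- function(fixture, window, which, side = "left", value = 1.5) {
  stopifnot(inherits(fixture, "stream_fixture"), length(window) == 2L,
            window[1L] <= window[2L], side %in% c("left", "right"))
  if (window[1L] == window[2L]) return(fixture)
  spec <- fixture$spec
  s <- fixture$truth$s
  edit_profile <- function(p, newval) {
    base <- eval_profile(p, s)
    inw <- s >= window[1L] & s <= window[2L]
    base[inw] <- newval
    cbind(s, base)
  }
  fld <- paste0(switch(which, M2 = "buffer", M3 = "erosion", M8 = "cover",
                       M7 = NULL, stop("unknown metric code for degrade: ", which)),
                "_", side)
  if (which == "M7") {
    dfld <- paste0("debris_", side)
    keep <- list()
    for (r in spec[[dfld]]) {
      if (r[2L] <= window[1L] || r[1L] >= window[2L]) { keep <- c(keep, list(r)); next }
      if (r[1L] < window[1L]) keep <- c(keep, list(c(r[1L], window[1L])))
      if (r[2L] > window[2L]) keep <- c(keep, list(c(window[2L], r[2L])))
    }
    spec[[dfld]] <- keep
  } else {
    spec[[fld]] <- edit_profile(spec[[fld]], switch(which, M2 = 0, M3 = value, M8 = 0))
  }
  generate_site(spec)
}
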