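#' Assessment configuration
#'
#' Bundles the tunable parameters of habitat parameter extraction and
#' multi-metric scoring.  All lengths are metres; percentiles are on the
#' 0--100 scale.
#'
#' @param n_transects number of transects used by transect-mode assessment.
#' @param delta_L transect spacing in metres; when `NULL` it is derived from
#'   the assessed stream length as `L0 / (n_transects - 1)`.
#' @param theta_bend_deg turning-angle threshold above which a centerline
#'   node counts as a bend.
#' @param bend_window_m arc-length window over which the turning angle is
#'   measured (noise immunity; must cover at least two station spacings).
#' @param depth_pct depth percentile a station must exceed to qualify as a
#'   pool (deep criterion).
#' @param vel_pct velocity-proxy percentile a station must fall below to
#'   qualify as a pool (slow criterion).
#' @param white_max maximum white-water pixel fraction at a pool station.
#' @param site_rule how a site-level category is derived from a continuous
#'   per-station metric: bin the length-weighted mean value (`"mean"`),
#'   take the modal station category (`"majority"`), or the worst
#'   (`"worst"`).
#' @param m7_max_dist_m maximum distance from the bank at which woody
#'   debris still counts as covering it.
#' @param side_ray_max_m maximum reach of the lateral rays used for the
#'   erosion/buffer/cover width measurements; layers further out are
#'   considered detached from the bank.
#' @return an object of class `assessment_config`.
#' @export
assessment_config <- function(n_transects = 14L, delta_L = NULL,
                              theta_bend_deg = 30, bend_window_m = 5,
                              depth_pct = 70, vel_pct = 30,
                              white_max = 0.10,
                              site_rule = c("mean", "majority", "worst"),
                              m7_max_dist_m = 2, side_ray_max_m = 100) {
  site_rule <- match.arg(site_rule)
  stopifnot(n_transects >= 2, theta_bend_deg > 0, theta_bend_deg < 180,
            depth_pct > 0, depth_pct < 100, vel_pct > 0, vel_pct < 100,
            white_max >= 0, white_max <= 1, bend_window_m > 0,
            m7_max_dist_m > 0, side_ray_max_m > 0)
  structure(list(n_transects = as.integer(n_transects), delta_L = delta_L,
                 theta_bend_deg = theta_bend_deg, bend_window_m = bend_window_m,
                 depth_pct = depth_pct, vel_pct = vel_pct,
                 white_max = white_max, site_rule = site_rule,
                 m7_max_dist_m = m7_max_dist_m, side_ray_max_m = side_ray_max_m),
            class = "assessment_config")
}

#' Flight configuration
#'
#' Operational constants of the two-level drone survey: altitudes, target
#' image overlaps, obstacle buffers, segment speeds and the battery budget.
#' Defaults follow common small-quadcopter survey practice: a 30 m
#' high-elevation sweep of the whole site and a 5 m low-elevation sweep of
#' the stream corridor, 75 % overlap (90 % over the focus corridor), 5 m
#' obstacle buffers, and a 20-minute battery of which 75 % is considered
#' usable after a 30 s liftoff/landing overhead.
#'
#' @param alt_high_m,alt_low_m flight altitudes above ground (m).
#' @param overlap_default,overlap_focus along-route image overlap fractions.
#' @param buffer_obstacle_m obstacle clearance buffer (m).
#' @param focus_corridor_m half-width of the stream focus corridor (m).
#' @param speed_survey_low,speed_transit_low,speed_survey_high,speed_transit_high
#'   segment speeds (m/s) for survey and transit edges at each elevation.
#' @param battery_min battery capacity in minutes.
#' @param usable_fraction fraction of the battery a route may consume.
#' @param overhead_s fixed liftoff-and-landing overhead (s).
#' @return an object of class `flight_config`.
#' @export
flight_config <- function(alt_high_m = 30, alt_low_m = 5,
                          overlap_default = 0.75, overlap_focus = 0.90,
                          buffer_obstacle_m = 5, focus_corridor_m = 10,
                          speed_survey_low = 1, speed_transit_low = 2,
                          speed_survey_high = 4, speed_transit_high = 8,
                          battery_min = 20, usable_fraction = 0.75,
                          overhead_s = 30) {
  stopifnot(overlap_default >= 0, overlap_default < 1,
            overlap_focus >= 0, overlap_focus < 1,
            speed_survey_low > 0, speed_transit_low > 0,
            speed_survey_high > 0, speed_transit_high > 0,
            usable_fraction > 0, usable_fraction <= 1,
            buffer_obstacle_m >= 0, focus_corridor_m >= 0)
  structure(as.list(environment()), class = "flight_config")
}

#' Camera model
#'
#' Pinhole field-of-view model used to convert altitude and target overlap
#' into sweep-line spacing.  Defaults approximate a small consumer
#' quadcopter camera (4:3 sensor, wide lens).
#'
#' @param fov_cross_track_deg,fov_along_track_deg full field-of-view angles
#'   (degrees) across and along the flight direction.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(fov_cross_track_deg = 81, fov_along_track_deg = 66) {
  stopifnot(fov_cross_track_deg > 0, fov_cross_track_deg < 180,
            fov_along_track_deg > 0, fov_along_track_deg < 180)
  structure(list(fov_cross_track_deg = fov_cross_track_deg,
                 fov_along_track_deg = fov_along_track_deg),
            class = "camera_model")
}

#' Site plan: flight boundary, obstacles and the stream channel
#'
#' @param boundary simple polygon (n x 2 matrix) bounding the flight area.
#' @param obstacles list of obstacle polygons.
#' @param obstacle_kind character vector (`"tree"` or `"building"`), one
#'   entry per obstacle.
#' @param stream_channel polygon outlining the stream channel.
#' @param focus_corridor_width_m focus-corridor width stored with the site.
#' @return an object of class `site_plan`.
#' @export
site_plan <- function(boundary, obstacles = list(), obstacle_kind = character(),
                      stream_channel = NULL, focus_corridor_width_m = 10) {
  boundary <- close_ring(boundary)
  if (nrow(boundary) < 3L || abs(polygon_area(boundary)) <= 0)
    stop("boundary must be a non-degenerate polygon")
  obstacles <- lapply(obstacles, close_ring)
  if (length(obstacle_kind) == 0L && length(obstacles) > 0L)
    obstacle_kind <- rep("tree", length(obstacles))
  stopifnot(length(obstacle_kind) == length(obstacles))
  if (!all(obstacle_kind %in% c("tree", "building")))
    stop("obstacle kinds must be 'tree' or 'building'")
  if (!is.null(stream_channel)) stream_channel <- close_ring(stream_channel)
  structure(list(boundary = boundary, obstacles = obstacles,
                 obstacle_kind = obstacle_kind, stream_channel = stream_channel,
                 focus_corridor_width_m = focus_corridor_width_m),
            class = "site_plan")
}

#' Bank geometry of a single-thread channel
#'
#' Left and right are defined facing downstream (inlet to outlet).  Bank
#' polylines are re-oriented to run inlet to outlet on construction; banks
#' that cross each other are rejected.
#'
#' @param left_bank,right_bank bank polylines (n x 2 matrices).
#' @param left_bank_top,right_bank_top bank-top polylines; may be `NULL`.
#' @param islands list of island polygons inside the channel.
#' @param inlet,outlet points marking the upstream and downstream ends.
#' @return an object of class `bank_geometry`.
#' @export
bank_geometry <- function(left_bank, right_bank,
                          left_bank_top = NULL, right_bank_top = NULL,
                          islands = list(), inlet, outlet) {
  orient <- function(line) {
    line <- coords(line)
    d_in <- sum((line[1L, ] - inlet)^2)
    d_out <- sum((line[1L, ] - outlet)^2)
    if (d_out < d_in) line[rev(seq_len(nrow(line))), , drop = FALSE] else line
  }
  left_bank <- orient(left_bank); right_bank <- orient(right_bank)
  if (!is.null(left_bank_top)) left_bank_top <- orient(left_bank_top)
  if (!is.null(right_bank_top)) right_bank_top <- orient(right_bank_top)
  if (polylines_cross(left_bank, right_bank))
    stop("left and right banks cross each other")
  obj <- structure(list(left_bank = left_bank, right_bank = right_bank,
                        left_bank_top = left_bank_top,
                        right_bank_top = right_bank_top,
                        islands = lapply(islands, close_ring),
                        inlet = as.numeric(inlet), outlet = as.numeric(outlet)),
                   class = "bank_geometry")
  ch <- channel_polygon(obj)
  for (isl in obj$islands)
    if (!all(point_in_polygon(isl, ch)))
      stop("island polygon lies outside the channel")
  obj
}

#' Channel polygon bounded by the two banks
#'
#' @param banks a [bank_geometry()] object.
#' @return closed ring (n x 2 matrix) of the channel area.
#' @export
channel_polygon <- function(banks) {
  close_ring(rbind(banks$left_bank,
                   banks$right_bank[rev(seq_len(nrow(banks$right_bank))), ]))
}

#' Habitat layer set
#'
#' Per-side delineated polygons plus the elevation inputs of the depth
#' model.  Each per-side entry is a list with components `left` and
#' `right`, each a list of polygons.
#'
#' @param erosion,veg_buffer,instream_cover,woody_debris per-side polygon
#'   lists (`list(left = list(...), right = list(...))`).
#' @param bed_points matrix/data frame with columns x, y, elev (m); riverbed
#'   elevation samples.
#' @param water_surface either a single elevation (m) or a data frame with
#'   columns `s`, `elev` giving the water-surface profile along the stream.
#' @param white_fraction optional data frame with columns `s`, `frac`
#'   (white-water pixel fraction in \[0, 1\]).
#' @return an object of class `layer_set`.
#' @export
layer_set <- function(erosion = sided(), veg_buffer = sided(),
                      instream_cover = sided(), woody_debris = sided(),
                      bed_points = NULL, water_surface = NULL,
                      white_fraction = NULL) {
  chk <- function(x, nm) {
    if (!is.list(x) || !all(c("left", "right") %in% names(x)))
      stop(sprintf("layer '%s' must be a list(left=, right=) of polygon lists", nm))
    lapply(x[c("left", "right")], function(side) lapply(side, close_ring))
  }
  erosion <- chk(erosion, "erosion"); veg_buffer <- chk(veg_buffer, "veg_buffer")
  instream_cover <- chk(instream_cover, "instream_cover")
  woody_debris <- chk(woody_debris, "woody_debris")
  if (!is.null(bed_points)) {
    bed_points <- as.data.frame(bed_points)
    if (!all(c("x", "y", "elev") %in% names(bed_points)))
      stop("bed_points needs columns x, y, elev")
  }
  if (!is.null(white_fraction)) {
    white_fraction <- as.data.frame(white_fraction)
    if (!all(c("s", "frac") %in% names(white_fraction)))
      stop("white_fraction needs columns s, frac")
    if (any(white_fraction$frac < 0 | white_fraction$frac > 1))
      stop("white_fraction values must lie in [0, 1]")
  }
  structure(list(erosion = erosion, veg_buffer = veg_buffer,
                 instream_cover = instream_cover, woody_debris = woody_debris,
                 bed_points = bed_points, water_surface = water_surface,
                 white_fraction = white_fraction),
            class = "layer_set")
}

#' Empty per-side polygon container
#' @param left,right lists of polygons assigned to each bank.
#' @return `list(left=, right=)`.
#' @export
sided <- function(left = list(), right = list()) list(left = left, right = right)

# Validate a station table: strictly increasing s, non-negative widths.
validate_stations <- function(records) {
  records <- as.data.frame(records)
  need <- c("s", "x", "y", "W", "D")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("station table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("station table is empty")
  if (any(duplicated(records$s))) stop("duplicated station arc length s")
  if (is.unsorted(records$s, strictly = TRUE)) stop("station s must be strictly increasing")
  wcols <- intersect(c("W", "D", "BT", "E_left", "E_right", "B_left", "B_right",
                       "F_left", "F_right"), names(records))
  for (cc in wcols)
    if (any(records[[cc]] < 0, na.rm = TRUE)) stop("negative value in column ", cc)
  if ("wet_fraction" %in% names(records) &&
      any(records$wet_fraction < -1e-9 | records$wet_fraction > 1 + 1e-9, na.rm = TRUE))
    stop("wet_fraction outside [0, 1]")
  records
}

#' @export
print.site_plan <- function(x, ...) {
  cat(sprintf("<site_plan> boundary area %.1f m^2, %d obstacle(s)%s\n",
              abs(polygon_area(x$boundary)), length(x$obstacles),
              if (is.null(x$stream_channel)) "" else ", stream channel present"))
  invisible(x)
}

#' @export
print.bank_geometry <- function(x, ...) {
  cat(sprintf("<bank_geometry> left %.1f m, right %.1f m, %d island(s)\n",
              polyline_length(x$left_bank), polyline_length(x$right_bank),
              length(x$islands)))
  invisible(x)
}
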