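# Per-station habitat parameters: shortest-chord wetted width, lateral
# widths (erosion, buffer, in-stream cover), bank-top width, depth from
# water-surface minus interpolated bed, wetted fraction, velocity proxy,
# pool detection and bank coverage fractions.

# Crossing of the line p + t*d with a polyline that is nearest to p
# (smallest |t|); NA when the line misses the polyline.
nearest_crossing_t <- function(p, d, line) {
  ts <- polyline_line_ts(p, d, line)
  if (length(ts) == 0L) return(NA_real_)
  ts[which.min(abs(ts))]
}

#' Shortest bank-to-bank chord through a centerline node
#'
#' Scans chord directions at 1 degree resolution (after a coarse pass) and
#' returns the minimal-length chord connecting the left and right banks
#' through the node.  The wetted width is the chord length minus any part
#' crossing an island.
#'
#' @param node length-2 point on the centerline, strictly inside the
#'   channel.
#' @param banks a [bank_geometry()].
#' @param s optional arc-length station recorded on the chord.
#' @return list with `W` (wetted width, m) and `chord` (a `transect_chord`:
#'   node, unit direction, signed line parameters `t_left`/`t_right` of the
#'   bank hits, chord `length` and `island_overlap_m`).
#' @export
width_at <- function(node, banks, s = NA_real_) {
  stopifnot(inherits(banks, "bank_geometry"))
  ch <- channel_polygon(banks)
  if (!point_in_polygon(rbind(node), ch))
    stop("node lies outside the channel")
  eval_angle <- function(phi) {
    d <- c(cos(phi), sin(phi))
    tl <- nearest_crossing_t(node, d, banks$left_bank)
    tr <- nearest_crossing_t(node, d, banks$right_bank)
    if (is.na(tl) || is.na(tr) || sign(tl) == sign(tr)) return(NULL)
    list(d = d, t_left = tl, t_right = tr, len = abs(tl) + abs(tr))
  }
  best <- NULL
  for (phi in seq(0, pi - 1e-9, by = 6 * pi / 180)) {
    cand <- eval_angle(phi)
    if (!is.null(cand) && (is.null(best) || cand$len < best$len)) {
      best <- cand; best$phi <- phi
    }
  }
  if (is.null(best)) stop("no bank-to-bank chord found through node")
  for (phi in best$phi + seq(-5, 5) * pi / 180) {
    cand <- eval_angle(phi %% pi)
    if (!is.null(cand) && cand$len < best$len) { best <- cand; best$phi <- phi }
  }
  tmin <- min(best$t_left, best$t_right); tmax <- max(best$t_left, best$t_right)
  overlap <- covered_length(node, best$d, banks$islands, tmin, tmax)
  chord <- structure(list(s = s, node = as.numeric(node), dir = best$d,
                          t_left = best$t_left, t_right = best$t_right,
                          length = best$len, island_overlap_m = overlap),
                     class = "transect_chord")
  list(W = best$len - overlap, chord = chord)
}

# Unit direction from the chord's node towards the given bank, plus the
# distance to that bank along it.
chord_side_ray <- function(chord, side) {
  t_side <- if (side == "left") chord$t_left else chord$t_right
  list(dir = chord$dir * sign(t_side), t_bank = abs(t_side))
}

#' Lateral layer width along a transect chord
#'
#' Measures how much of the chord's supporting ray on the given side (from
#' the centerline node outward through the bank) lies inside the layer
#' polygons.  The in-channel part of the ray counts in full (for layers
#' such as in-stream cover); beyond the bank, covered intervals are
#' accumulated only while they chain from the bank with gaps of at most
#' `gap_m`, so disjoint patches near the bank add up while detached
#' polygons further out -- including riparian zones of other meander limbs
#' the ray may eventually pierce -- are ignored.  The ray reaches at most
#' `max_m` beyond the bank.
#'
#' @param chord a `transect_chord` from [width_at()].
#' @param layer list of polygons.
#' @param side `"left"` or `"right"`.
#' @param max_m maximum reach beyond the bank (m).
#' @param gap_m maximum uncovered gap across which the measurement
#'   continues beyond the bank (m).
#' @return width in metres.
#' @export
side_width <- function(chord, layer, side = c("left", "right"), max_m = 100,
                       gap_m = 1) {
  side <- match.arg(side)
  if (length(layer) == 0L) return(0)
  ray <- chord_side_ray(chord, side)
  iv <- do.call(rbind, lapply(layer, function(pg)
    line_polygon_intervals(chord$node, ray$dir, pg)))
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  iv[, 1L] <- pmax(iv[, 1L], 0)
  iv[, 2L] <- pmin(iv[, 2L], ray$t_bank + max_m)
  iv <- iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  iv <- merge_intervals(iv)
  # in-channel part: union between node and bank
  inside <- pmin(iv[, 2L], ray$t_bank) - pmax(iv[, 1L], 0)
  total <- sum(pmax(inside, 0))
  # beyond the bank: chain outward while gaps stay below gap_m
  cur <- ray$t_bank
  for (k in seq_len(nrow(iv))) {
    a <- max(iv[k, 1L], ray$t_bank); b <- iv[k, 2L]
    if (b <= ray$t_bank) next
    if (a > cur + gap_m) break
    total <- total + (b - a)
    cur <- max(cur, b)
  }
  total
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] <= out[nrow(out), 2L])
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[i, 2L])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

#' Bank-top width along a transect chord
#'
#' Distance between the crossings of the chord's supporting line with the
#' left and right bank-top polylines.  When either bank top is missing
#' within `max_m` of the bank the value is `NA` with attribute
#' `missing_side` naming the side(s).
#'
#' @param chord a `transect_chord`.
#' @param banks a [bank_geometry()] carrying bank-top polylines.
#' @param max_m search distance beyond each bank (m).
#' @return bank-top width (m), `NA` when flagged missing.
#' @export
bank_top_width <- function(chord, banks, max_m = 100) {
  one <- function(side) {
    top <- banks[[paste0(side, "_bank_top")]]
    if (is.null(top)) return(NA_real_)
    ray <- chord_side_ray(chord, side)
    ts <- polyline_line_ts(chord$node, ray$dir, top)
    ts <- ts[ts > 0 & ts <= ray$t_bank + max_m]
    if (length(ts) == 0L) NA_real_ else min(ts)
  }
  tl <- one("left"); tr <- one("right")
  if (is.na(tl) || is.na(tr)) {
    miss <- c("left", "right")[c(is.na(tl), is.na(tr))]
    return(structure(NA_real_, missing_side = miss))
  }
  tl + tr
}

#' Depth series along the centerline
#'
#' Bed elevation is linearly interpolated in arc length between the
#' projections of the bed sample points onto the centerline; depth is the
#' water-surface elevation minus the bed.  Negative depths are clipped to
#' zero and counted.
#'
#' @param cl a `centerline`.
#' @param water_surface constant elevation (m) or data frame `(s, elev)`.
#' @param bed_points data frame with columns x, y, elev.
#' @return list with `D` (depth per centerline node, m) and `n_clipped`.
#' @export
depth_series <- function(cl, water_surface, bed_points) {
  stopifnot(inherits(cl, "centerline"))
  bed_points <- as.data.frame(bed_points)
  if (is.null(bed_points) || nrow(bed_points) < 2L)
    stop("at least two bed points are required")
  s_bed <- vapply(seq_len(nrow(bed_points)), function(i)
    nearest_on_polyline(c(bed_points$x[i], bed_points$y[i]), cl$nodes)$s, 1)
  ord <- order(s_bed)
  bed <- stats::approx(s_bed[ord], bed_points$elev[ord], xout = cl$s,
                       rule = 2, ties = mean)$y
  ws <- if (is.numeric(water_surface) && length(water_surface) == 1L)
    rep(water_surface, length(cl$s))
  else stats::approx(water_surface$s, water_surface$elev, xout = cl$s, rule = 2)$y
  D <- ws - bed
  n_clipped <- sum(D < 0)
  if (n_clipped > 0L)
    warning(n_clipped, " station(s) with water surface below bed; depth clipped to 0")
  list(D = pmax(D, 0), n_clipped = n_clipped)
}

#' Wetted fraction of a transect chord
#'
#' Fraction of the in-channel chord not occupied by islands or delineated
#' dry areas.
#'
#' @param chord a `transect_chord`.
#' @param banks a [bank_geometry()] (supplies islands).
#' @param dry_polygons additional dry-area polygons.
#' @return fraction in \[0, 1\].
#' @export
wet_fraction_at <- function(chord, banks, dry_polygons = list()) {
  tmin <- min(chord$t_left, chord$t_right); tmax <- max(chord$t_left, chord$t_right)
  total <- tmax - tmin
  dry <- covered_length(chord$node, chord$dir,
                        c(banks$islands, dry_polygons), tmin, tmax)
  max(0, min(1, (total - dry) / total))
}

#' Relative velocity proxy from continuity
#'
#' With discharge roughly constant along a reach, section-averaged velocity
#' scales as `Q / (W * D)`.  Only the ordering of values is meaningful; the
#' reference discharge cancels out of percentile-based comparisons.
#'
#' @param W,D wetted width and mean depth (m); vectorised.
#' @param reference_discharge arbitrary constant.
#' @return dimensionless proxy; `NA` where `W * D` is zero.
#' @export
velocity_proxy <- function(W, D, reference_discharge = 1) {
  a <- W * D
  ifelse(is.na(a) | a <= 0, NA_real_, reference_discharge / a)
}

#' Detect pools from the station series
#'
#' A station is pool-flagged when its depth exceeds the `depth_pct`
#' percentile, its velocity proxy falls below the `vel_pct` percentile
#' (both strict), and its white-water fraction is below `white_max` (this
#' criterion is skipped with a warning when no white fractions are
#' available).  Maximal runs of flagged stations become pool intervals;
#' runs separated by less than one median station spacing merge.
#'
#' @param records station data frame with columns `s`, `D`, `v_proxy` and
#'   optionally `white_fraction`.
#' @param cfg an [assessment_config()].
#' @return data frame with columns `s_start`, `s_end` (sorted, disjoint).
#' @export
detect_pools <- function(records, cfg = assessment_config()) {
  records <- as.data.frame(records)
  if (nrow(records) < 10L) stop("pool detection needs at least 10 stations")
  qD <- stats::quantile(records$D, cfg$depth_pct / 100, type = 7, names = FALSE)
  qV <- stats::quantile(records$v_proxy, cfg$vel_pct / 100, type = 7,
                        names = FALSE, na.rm = TRUE)
  flag <- records$D > qD & !is.na(records$v_proxy) & records$v_proxy < qV
  wf <- records$white_fraction
  if (is.null(wf) || all(is.na(wf))) {
    warning("white-water fractions unavailable; pool criterion reduced to depth and velocity")
  } else {
    flag <- flag & !is.na(wf) & wf < cfg$white_max
  }
  out <- data.frame(s_start = numeric(0), s_end = numeric(0))
  if (!any(flag)) return(out)
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values))
    out <- rbind(out, data.frame(s_start = records$s[starts[k]],
                                 s_end = records$s[ends[k]]))
  gap_tol <- stats::median(diff(records$s))
  merged <- out[1L, ]
  for (i in seq_len(nrow(out))[-1L]) {
    if (out$s_start[i] - merged$s_end[nrow(merged)] < gap_tol)
      merged$s_end[nrow(merged)] <- out$s_end[i]
    else merged <- rbind(merged, out[i, ])
  }
  rownames(merged) <- NULL
  merged
}

#' Fraction of a bank lying within reach of a habitat layer
#'
#' The bank is walked at sub-metre resolution; a location counts as
#' covered when the nearest layer polygon lies within `max_dist_m`.
#'
#' @param bank bank polyline.
#' @param layer list of polygons.
#' @param max_dist_m coverage distance (m).
#' @param step sampling step along the bank (m).
#' @return fraction of bank arc length in \[0, 1\].
#' @export
coverage_fraction <- function(bank, layer, max_dist_m = 2, step = 0.5) {
  bank <- coords(bank)
  if (nrow(bank) < 2L) stop("degenerate bank polyline")
  if (length(layer) == 0L) return(0)
  dense <- densify_polyline(bank, step)
  mids <- (dense[-1L, , drop = FALSE] + dense[-nrow(dense), , drop = FALSE]) / 2
  lens <- seg_lengths(dense)
  covered <- vapply(seq_len(nrow(mids)), function(i)
    dist_point_polygons(mids[i, ], layer) <= max_dist_m, logical(1))
  sum(lens[covered]) / sum(lens)
}

#' Extract the full station table for a channel
#'
#' Runs the per-station measurements (shortest-chord width, lateral
#' erosion/buffer/cover widths, bank-top width, wetted fraction) at every
#' centerline node, attaches the depth series, white-water fractions and
#' the velocity proxy, and returns the assembled station table.
#'
#' @param banks a [bank_geometry()].
#' @param layers a [layer_set()].
#' @param cl a `centerline` from [extract_centerline()].
#' @param cfg an [assessment_config()].
#' @return data frame with the columns documented in
#'   [write_station_table()].
#' @export
extract_stations <- function(banks, layers, cl, cfg = assessment_config()) {
  stopifnot(inherits(banks, "bank_geometry"), inherits(layers, "layer_set"),
            inherits(cl, "centerline"))
  n <- nrow(cl$nodes)
  dep <- depth_series(cl, layers$water_surface, layers$bed_points)
  W <- BT <- El <- Er <- Bl <- Br <- Fl <- Fr <- wetf <- rep(NA_real_, n)
  # the first and last nodes sit on the channel end edges where no
  # bank-to-bank chord exists; stations cover the interior nodes
  interior <- if (n > 2L) 2:(n - 1L) else seq_len(n)
  for (i in interior) {
    wa <- width_at(cl$nodes[i, ], banks, s = cl$s[i])
    W[i] <- wa$W
    ch <- wa$chord
    El[i] <- side_width(ch, layers$erosion$left, "left", cfg$side_ray_max_m)
    Er[i] <- side_width(ch, layers$erosion$right, "right", cfg$side_ray_max_m)
    Bl[i] <- side_width(ch, layers$veg_buffer$left, "left", cfg$side_ray_max_m)
    Br[i] <- side_width(ch, layers$veg_buffer$right, "right", cfg$side_ray_max_m)
    Fl[i] <- side_width(ch, layers$instream_cover$left, "left", cfg$side_ray_max_m)
    Fr[i] <- side_width(ch, layers$instream_cover$right, "right", cfg$side_ray_max_m)
    BT[i] <- suppressWarnings(as.numeric(bank_top_width(ch, banks)))
    wetf[i] <- wet_fraction_at(ch, banks)
  }
  white <- if (!is.null(layers$white_fraction))
    stats::approx(layers$white_fraction$s, layers$white_fraction$frac,
                  xout = cl$s, rule = 2)$y
  else rep(NA_real_, n)
  out <- data.frame(
    s = cl$s, x = cl$nodes[, 1L], y = cl$nodes[, 2L], W = W, D = dep$D,
    BT = BT, E_left = El, E_right = Er, B_left = Bl, B_right = Br,
    F_left = Fl, F_right = Fr, wet_fraction = wetf, white_fraction = white,
    v_proxy = velocity_proxy(W, dep$D))
  validate_stations(out[interior, ])
}
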