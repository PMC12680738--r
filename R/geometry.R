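# Planar geometry kernel.
#
# All geometries live in one projected metric plane: points are length-2
# numeric vectors, polylines and polygon rings are n x 2 matrices (rings are
# stored open, i.e. first vertex is not repeated).  Even-odd semantics are
# used throughout for polygon interiors.

coords <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("coordinate matrix needs two columns")
  m <- m[, 1:2, drop = FALSE]
  dimnames(m) <- NULL
  m
}

close_ring <- function(poly) {
  poly <- coords(poly)
  if (nrow(poly) > 1L && all(poly[1L, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

seg_lengths <- function(line) {
  line <- coords(line)
  sqrt(diff(line[, 1L])^2 + diff(line[, 2L])^2)
}

polyline_length <- function(line) sum(seg_lengths(line))

#' @noRd
cumulative_s <- function(line) c(0, cumsum(seg_lengths(line)))

# Point at arc length s (vectorised over s); clamps to the endpoints.
point_along <- function(line, s) {
  line <- coords(line)
  cs <- cumulative_s(line)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(line) - 1L)
  len <- cs[i + 1L] - cs[i]
  f <- ifelse(len > 0, (s - cs[i]) / len, 0)
  cbind(line[i, 1L] + f * (line[i + 1L, 1L] - line[i, 1L]),
        line[i, 2L] + f * (line[i + 1L, 2L] - line[i, 2L]))
}

# Insert vertices so that no segment exceeds `step`.
densify_polyline <- function(line, step) {
  line <- coords(line)
  if (nrow(line) < 2L) return(line)
  out <- list(line[1L, , drop = FALSE])
  for (i in seq_len(nrow(line) - 1L)) {
    a <- line[i, ]; b <- line[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    f <- seq_len(n) / n
    out[[length(out) + 1L]] <- cbind(a[1L] + f * (b[1L] - a[1L]),
                                     a[2L] + f * (b[2L] - a[2L]))
  }
  do.call(rbind, out)
}

# Resample at (approximately) uniform arc-length spacing, endpoints kept.
resample_polyline <- function(line, spacing) {
  line <- coords(line)
  L <- polyline_length(line)
  n <- max(2L, ceiling(L / spacing) + 1L)
  point_along(line, seq(0, L, length.out = n))
}

polygon_area <- function(poly) {
  poly <- close_ring(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(seq_len(nrow(poly))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

ensure_ccw <- function(poly) {
  poly <- close_ring(poly)
  if (polygon_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Even-odd point-in-polygon, vectorised over points (edge loop).
point_in_polygon <- function(pts, poly) {
  pts <- coords(pts); poly <- close_ring(poly)
  n <- nrow(poly)
  px <- pts[, 1L]; py <- pts[, 2L]
  inside <- logical(length(px))
  xs <- poly[, 1L]; ys <- poly[, 2L]
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    crosses <- (ys[i] > py) != (ys[j] > py)
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
      flip <- crosses
      flip[crosses] <- xint > px[crosses]
      inside <- xor(inside, flip)
    }
  }
  inside
}

# Distance from one point to every segment of a polyline; returns the
# minimum together with the nearest point and its arc-length station.
nearest_on_polyline <- function(p, line) {
  line <- coords(line)
  ax <- line[-nrow(line), 1L]; ay <- line[-nrow(line), 2L]
  bx <- line[-1L, 1L];         by <- line[-1L, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- ((p[1L] - ax) * dx + (p[2L] - ay) * dy) / ifelse(len2 > 0, len2, 1)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx; qy <- ay + t * dy
  d2 <- (p[1L] - qx)^2 + (p[2L] - qy)^2
  i <- which.min(d2)
  cs <- cumulative_s(line)
  list(point = c(qx[i], qy[i]), dist = sqrt(d2[i]),
       s = cs[i] + t[i] * sqrt(len2[i]), seg = i)
}

dist_point_polyline <- function(p, line) nearest_on_polyline(p, line)$dist

# 0 inside, boundary distance outside.
dist_point_polygon <- function(p, poly) {
  poly <- close_ring(poly)
  if (point_in_polygon(rbind(p), poly)) return(0)
  dist_point_polyline(p, rbind(poly, poly[1L, , drop = FALSE]))
}

dist_point_polygons <- function(p, polys) {
  if (length(polys) == 0L) return(Inf)
  min(vapply(polys, function(pg) dist_point_polygon(p, pg), numeric(1)))
}

# Parameters t of the crossings of the infinite line p + t*d with the edges
# of an (open) polyline.  Works in a frame rotated so d is the x axis.
polyline_line_ts <- function(p, d, line, closed = FALSE) {
  line <- coords(line)
  if (closed) line <- rbind(close_ring(line), close_ring(line)[1L, , drop = FALSE])
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("zero direction vector")
  u <- d / nd
  rx <- (line[, 1L] - p[1L]) * u[1L] + (line[, 2L] - p[2L]) * u[2L]
  ry <- -(line[, 1L] - p[1L]) * u[2L] + (line[, 2L] - p[2L]) * u[1L]
  n <- length(rx)
  ya <- ry[-n]; yb <- ry[-1L]
  crosses <- (ya > 0) != (yb > 0)
  if (!any(crosses)) return(numeric(0))
  xa <- rx[-n][crosses]; xb <- rx[-1L][crosses]
  f <- ya[crosses] / (ya[crosses] - yb[crosses])
  sort(xa + f * (xb - xa))
}

# Inside-intervals (even-odd) of the line p + t*d through a polygon,
# returned as a 2-column matrix of [t_enter, t_exit].
line_polygon_intervals <- function(p, d, poly) {
  ts <- polyline_line_ts(p, d, poly, closed = TRUE)
  if (length(ts) < 2L) return(matrix(numeric(0), ncol = 2L))
  if (length(ts) %% 2L == 1L) ts <- ts[-length(ts)]  # grazing-vertex guard
  matrix(ts, ncol = 2L, byrow = TRUE)
}

# Total length of the part of [t0, t1] that lies inside any polygon of a
# list (union of the clipped intervals).
covered_length <- function(p, d, polys, t0, t1) {
  if (length(polys) == 0L || t1 <= t0) return(0)
  iv <- do.call(rbind, lapply(polys, function(pg) line_polygon_intervals(p, d, pg)))
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  iv[, 1L] <- pmax(iv[, 1L], t0); iv[, 2L] <- pmin(iv[, 2L], t1)
  iv <- iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  union_interval_length(iv)
}

union_interval_length <- function(iv) {
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  tot <- 0; cur_a <- iv[1L, 1L]; cur_b <- iv[1L, 2L]
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv[i, 1L] > cur_b) { tot <- tot + (cur_b - cur_a); cur_a <- iv[i, 1L]; cur_b <- iv[i, 2L] }
    else cur_b <- max(cur_b, iv[i, 2L])
  }
  tot + (cur_b - cur_a)
}

segments_cross <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1; d2 <- b2 - b1
  den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
  if (abs(den) < 1e-12) return(FALSE)
  t <- ((b1[1L] - a1[1L]) * d2[2L] - (b1[2L] - a1[2L]) * d2[1L]) / den
  u <- ((b1[1L] - a1[1L]) * d1[2L] - (b1[2L] - a1[2L]) * d1[1L]) / den
  t > 0 && t < 1 && u > 0 && u < 1
}

# TRUE when any segment of line1 properly crosses any segment of line2.
polylines_cross <- function(line1, line2) {
  line1 <- coords(line1); line2 <- coords(line2)
  for (i in seq_len(nrow(line1) - 1L))
    for (j in seq_len(nrow(line2) - 1L))
      if (segments_cross(line1[i, ], line1[i + 1L, ], line2[j, ], line2[j + 1L, ]))
        return(TRUE)
  FALSE
}

# Left-offset of a polyline by distance d (vertex-bisector normals).  Exact
# for smooth, densified lines with |d| below the local curvature radius.
offset_polyline <- function(line, d) {
  line <- coords(line)
  n <- nrow(line)
  if (n < 2L) stop("polyline needs at least 2 vertices")
  dx <- diff(line[, 1L]); dy <- diff(line[, 2L])
  len <- sqrt(dx^2 + dy^2)
  tx <- dx / len; ty <- dy / len
  # per-vertex tangent: average of adjacent segment tangents
  vtx <- c(tx[1L], (tx[-1L] + tx[-length(tx)]) / 2, tx[length(tx)])
  vty <- c(ty[1L], (ty[-1L] + ty[-length(ty)]) / 2, ty[length(ty)])
  vn <- sqrt(vtx^2 + vty^2); vtx <- vtx / vn; vty <- vty / vn
  cbind(line[, 1L] - d * vty, line[, 2L] + d * vtx)
}

# Outward offset ("buffer") of a simple polygon by d > 0 with round joins.
# Arcs are discretised at `arc_step_deg`.  Reflex vertices get a miter
# intersection; valid while d stays below the local feature size.
buffer_polygon <- function(poly, d, arc_step_deg = 6) {
  stopifnot(d >= 0)
  poly <- ensure_ccw(poly)
  if (d == 0) return(poly)
  n <- nrow(poly)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  ex <- poly[nxt, 1L] - poly[, 1L]; ey <- poly[nxt, 2L] - poly[, 2L]
  el <- sqrt(ex^2 + ey^2)
  keep <- el > 1e-12
  if (!all(keep)) return(buffer_polygon(poly[keep, , drop = FALSE], d, arc_step_deg))
  # outward (right-hand, since CCW) normal of each edge
  nxv <- ey / el; nyv <- -ex / el
  out <- list()
  step <- arc_step_deg * pi / 180
  for (i in seq_len(n)) {
    j <- prv[i]
    # offset endpoint of incoming edge j and start point of outgoing edge i
    p_in <- c(poly[i, 1L] + d * nxv[j], poly[i, 2L] + d * nyv[j])
    p_out <- c(poly[i, 1L] + d * nxv[i], poly[i, 2L] + d * nyv[i])
    cross <- ex[j] * ey[i] - ey[j] * ex[i]
    if (cross > 1e-12) {            # convex vertex: arc from n_j to n_i
      a0 <- atan2(nyv[j], nxv[j]); a1 <- atan2(nyv[i], nxv[i])
      dang <- a1 - a0
      if (dang < 0) dang <- dang + 2 * pi
      k <- max(1L, ceiling(dang / step))
      ang <- a0 + dang * (0:k) / k
      out[[length(out) + 1L]] <- cbind(poly[i, 1L] + d * cos(ang),
                                       poly[i, 2L] + d * sin(ang))
    } else if (cross < -1e-12) {    # reflex vertex: miter the two offset lines
      a1p <- c(poly[j, 1L] + d * nxv[j], poly[j, 2L] + d * nyv[j])
      den <- ex[j] * ey[i] - ey[j] * ex[i]
      t <- ((p_out[1L] - a1p[1L]) * ey[i] - (p_out[2L] - a1p[2L]) * ex[i]) / den
      out[[length(out) + 1L]] <- rbind(c(a1p[1L] + t * ex[j], a1p[2L] + t * ey[j]))
    } else {
      out[[length(out) + 1L]] <- rbind(p_out)
    }
  }
  close_ring(do.call(rbind, out))
}

polygon_is_convex <- function(poly) {
  poly <- ensure_ccw(poly)
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  e <- poly[nxt, , drop = FALSE] - poly
  cr <- e[, 1L] * e[nxt, 2L] - e[, 2L] * e[nxt, 1L]
  all(cr >= -1e-9 * max(abs(e)))
}

# Sutherland-Hodgman clipping of an arbitrary subject ring by a convex ring.
convex_clip <- function(subject, clip) {
  clip <- ensure_ccw(clip)
  out <- close_ring(subject)
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    inside <- function(p) (p[1L] - a[1L]) * ey - (p[2L] - a[2L]) * ex <= 1e-12
    res <- list()
    m <- nrow(out)
    for (k in seq_len(m)) {
      cur <- out[k, ]; nxt <- out[if (k == m) 1L else k + 1L, ]
      ci <- inside(cur); ni <- inside(nxt)
      if (ci) res[[length(res) + 1L]] <- cur
      if (ci != ni) {
        dcx <- nxt[1L] - cur[1L]; dcy <- nxt[2L] - cur[2L]
        den <- dcx * ey - dcy * ex
        t <- ((a[1L] - cur[1L]) * ey - (a[2L] - cur[2L]) * ex) / den
        res[[length(res) + 1L]] <- c(cur[1L] + t * dcx, cur[2L] + t * dcy)
      }
    }
    out <- if (length(res)) do.call(rbind, res) else matrix(numeric(0), ncol = 2L)
  }
  out
}

# Does the axis-aligned square centred at (cx, cy) with half-width h
# intersect the polygon (boundary or interior)?
square_intersects_polygon <- function(cx, cy, h, poly) {
  poly <- close_ring(poly)
  sq <- rbind(c(cx - h, cy - h), c(cx + h, cy - h), c(cx + h, cy + h), c(cx - h, cy + h))
  if (any(point_in_polygon(sq, poly))) return(TRUE)
  inx <- poly[, 1L] >= cx - h & poly[, 1L] <= cx + h &
         poly[, 2L] >= cy - h & poly[, 2L] <= cy + h
  if (any(inx)) return(TRUE)
  ring <- rbind(poly, poly[1L, , drop = FALSE])
  sqc <- rbind(sq, sq[1L, , drop = FALSE])
  polylines_cross(sqc, ring)
}

bbox_of <- function(x) {
  m <- coords(x)
  c(xmin = min(m[, 1L]), ymin = min(m[, 2L]),
    xmax = max(m[, 1L]), ymax = max(m[, 2L]))
}
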