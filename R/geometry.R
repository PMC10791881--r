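#' Exact planar geometry for circular-buffer extraction
#'
#' All buffer predictors are defined on closed discs in a projected metric
#' CRS. The primitives here are closed-form (no rasterisation of the disc):
#' disc/polygon intersection area via per-edge sector decomposition,
#' chord-clipped segment lengths, point-to-segment distances, and exact
#' disc/axis-aligned-rectangle areas for raster cell weighting.
#'
#' @name geometry
#' @keywords internal
NULL

#' Signed area of a polygon (shoelace formula)
#'
#' @param xy two-column matrix of vertices (closed or open ring).
#' @return Signed area; positive for counter-clockwise rings.
#' @export
polygon_area <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) return(0)
  # drop duplicated closing vertex
  if (isTRUE(all.equal(xy[1, ], xy[n, ], check.attributes = FALSE))) {
    xy <- xy[-n, , drop = FALSE]
    n <- n - 1L
    if (n < 3) return(0)
  }
  j <- c(2:n, 1L)
  sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]) / 2
}

#' Clip a convex or simple polygon by the half-plane a*x + b*y <= c
#'
#' Sutherland-Hodgman step; returns a matrix of vertices (possibly 0 rows).
#'
#' @param xy two-column vertex matrix (open ring).
#' @param a,b,c half-plane coefficients.
#' @return Clipped polygon vertex matrix.
#' @export
clip_halfplane <- function(xy, a, b, c) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n == 0) return(xy)
  val <- a * xy[, 1] + b * xy[, 2] - c
  keep_in <- val <= 0
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep_in[i]) out <- rbind(out, xy[i, ])
    if (xor(keep_in[i], keep_in[j])) {
      t <- val[i] / (val[i] - val[j])
      out <- rbind(out, xy[i, ] + t * (xy[j, ] - xy[i, ]))
    }
  }
  out
}

# Signed contribution of edge p1 -> p2 to the area of the intersection of
# the polygon with a disc of radius r centred at the origin.  Sub-segments
# inside the disc contribute the triangle (0, a, b); sub-segments outside
# contribute the circular sector between their direction angles.
.edge_disc_contrib <- function(p1, p2, r) {
  d <- p2 - p1
  aa <- sum(d * d)
  if (aa == 0) return(0)
  bb <- 2 * sum(p1 * d)
  cc <- sum(p1 * p1) - r * r
  disc <- bb * bb - 4 * aa * cc
  ts <- c(0, 1)
  if (disc > 0) {
    sq <- sqrt(disc)
    t1 <- (-bb - sq) / (2 * aa)
    t2 <- (-bb + sq) / (2 * aa)
    ts <- sort(unique(c(0, 1, t1[t1 > 0 & t1 < 1], t2[t2 > 0 & t2 < 1])))
  }
  total <- 0
  for (k in seq_len(length(ts) - 1L)) {
    ta <- ts[k]; tb <- ts[k + 1L]
    pa <- p1 + ta * d
    pb <- p1 + tb * d
    pm <- p1 + 0.5 * (ta + tb) * d
    if (sum(pm * pm) <= r * r) {
      total <- total + (pa[1] * pb[2] - pb[1] * pa[2]) / 2
    } else {
      ang <- atan2(pa[1] * pb[2] - pb[1] * pa[2], sum(pa * pb))
      total <- total + 0.5 * r * r * ang
    }
  }
  total
}

#' Exact area of the intersection of a disc and a simple polygon
#'
#' Green's-theorem sector decomposition: each polygon edge contributes either
#' a triangle with the disc centre (sub-segment inside the disc) or a
#' circular sector (sub-segment outside).  Exact to floating-point precision
#' for any simple polygon; the polygon need not be convex.
#'
#' @param xy two-column vertex matrix (open or closed ring, either winding).
#' @param cx,cy disc centre.
#' @param r disc radius (> 0).
#' @return Intersection area (>= 0).
#' @export
disc_polygon_area <- function(xy, cx, cy, r) {
  stopifnot(r > 0)
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n > 1 && isTRUE(all.equal(xy[1, ], xy[n, ], check.attributes = FALSE))) {
    xy <- xy[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) return(0)
  xy <- sweep(xy, 2, c(cx, cy))
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    total <- total + .edge_disc_contrib(xy[i, ], xy[j, ], r)
  }
  abs(total)
}

#' Length of line segments clipped to a disc (chord lengths)
#'
#' Vectorised over segments.  A segment through the centre of a disc of
#' radius r contributes min(2r, its length inside).
#'
#' @param x1,y1,x2,y2 segment endpoints (vectors).
#' @param cx,cy disc centre.
#' @param r disc radius.
#' @return Vector of in-disc lengths (m).
#' @export
segment_length_in_disc <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  fx <- x1 - cx; fy <- y1 - cy
  aa <- dx * dx + dy * dy
  bb <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- bb * bb - 4 * aa * cc
  len <- sqrt(aa)
  out <- numeric(length(x1))
  ok <- disc > 0 & aa > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax((-bb[ok] - sq) / (2 * aa[ok]), 0)
    t2 <- pmin((-bb[ok] + sq) / (2 * aa[ok]), 1)
    out[ok] <- pmax(t2 - t1, 0) * len[ok]
  }
  # degenerate zero-length segments contribute nothing
  out
}

#' Euclidean distance from a point to each of a set of segments
#'
#' @param px,py the point.
#' @param x1,y1,x2,y2 segment endpoints (vectors).
#' @return Vector of distances (m).
#' @export
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  aa <- dx * dx + dy * dy
  t <- ifelse(aa > 0, ((px - x1) * dx + (py - y1) * dy) / aa, 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx; qy <- y1 + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

# Antiderivative of sqrt(r^2 - u^2) on [-r, r].
.H <- function(u, r) {
  u <- pmin(pmax(u, -r), r)
  0.5 * (u * sqrt(pmax(r * r - u * u, 0)) + r * r * asin(pmin(pmax(u / r, -1), 1)))
}

# J(x, y) = integral_{-r}^{x} clamp(y, -h(u), h(u)) du with h(u)=sqrt(r^2-u^2):
# the building block for exact disc/rectangle intersection areas. Vectorised.
.J <- function(x, y, r) {
  xh <- pmin(pmax(x, -r), r)
  Hr <- .H(-r, r)
  full <- .H(xh, r) - Hr
  # |y| >= r: whole half-width
  res <- ifelse(y >= 0, full, -full)
  mid <- abs(y) < r
  if (any(mid)) {
    yc <- y[mid]
    xm <- xh[mid]
    rr <- r
    xc <- sqrt(pmax(rr * rr - yc * yc, 0))
    outer <- (.H(pmin(xm, -xc), rr) - Hr) + (.H(pmax(xm, xc), rr) - .H(xc, rr))
    middle <- yc * (pmin(pmax(xm, -xc), xc) + xc)
    res[mid] <- ifelse(yc >= 0, outer, -outer) + middle
  }
  res
}

#' Exact area of intersection of a disc and axis-aligned rectangles
#'
#' Closed-form (inclusion-exclusion over the four corners of each rectangle
#' with the clamped-chord antiderivative); vectorised over rectangles.
#' This is what makes raster-cell weighting in population buffers exact
#' rather than centre-in-disc approximate.
#'
#' @param cx,cy disc centre; \code{r} its radius.
#' @param xlo,xhi,ylo,yhi rectangle bounds (vectors).
#' @return Vector of intersection areas.
#' @export
disc_rect_area <- function(cx, cy, r, xlo, xhi, ylo, yhi) {
  x1 <- xlo - cx; x2 <- xhi - cx
  y1 <- ylo - cy; y2 <- yhi - cy
  a <- .J(x2, y2, r) - .J(x1, y2, r) - .J(x2, y1, r) + .J(x1, y1, r)
  pmax(a, 0)
}
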