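# Planar geometry kernel shared by the synthetic generator and the GIS
# predictor extraction. Coordinates are metres on a local planar grid; study
# extents are small enough (<~100 km) that no geodesy is needed.

#' Distance from a point to a set of line segments
#'
#' Vectorised over segments: returns, for one point, the Euclidean distance to
#' every segment `(x0,y0)-(x1,y1)`.
#'
#' @param px,py point coordinates (scalars, metres).
#' @param x0,y0,x1,y1 numeric vectors of segment endpoints.
#' @return numeric vector of distances (metres).
#' @export
dist_point_segments <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  l2 <- dx * dx + dy * dy
  t <- ((px - x0) * dx + (py - y0) * dy) / ifelse(l2 > 0, l2, 1)
  t[l2 == 0] <- 0
  t <- clamp(t, 0, 1)
  qx <- x0 + t * dx
  qy <- y0 + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Length of a segment inside a disc
#'
#' Closed-form chord computation: length of the part of each segment
#' `(x0,y0)-(x1,y1)` lying inside the disc of radius `r` centred at `(cx,cy)`.
#' Vectorised over segments.
#'
#' @param cx,cy disc centre (metres).
#' @param r disc radius (metres, > 0).
#' @param x0,y0,x1,y1 segment endpoint vectors.
#' @return numeric vector of intersected lengths (metres).
#' @export
segment_disc_length <- function(cx, cy, r, x0, y0, x1, y1) {
  vx <- x1 - x0
  vy <- y1 - y0
  wx <- x0 - cx
  wy <- y0 - cy
  a <- vx * vx + vy * vy
  b <- 2 * (vx * wx + vy * wy)
  cc <- wx * wx + wy * wy - r * r
  disc <- b * b - 4 * a * cc
  len <- numeric(length(a))
  ok <- disc > 0 & a > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- clamp((-b[ok] - sq) / (2 * a[ok]), 0, 1)
    t2 <- clamp((-b[ok] + sq) / (2 * a[ok]), 0, 1)
    len[ok] <- (t2 - t1) * sqrt(a[ok])
  }
  len
}

segment_lengths <- function(x0, y0, x1, y1) sqrt((x1 - x0)^2 + (y1 - y0)^2)
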