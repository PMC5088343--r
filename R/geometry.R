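# Planar geometry primitives. Coordinates are always longitude-first, in
# degrees; polygons are lists of closed rings (first vertex == last), each
# ring an n x 2 matrix. Containment uses the even-odd rule with boundary
# points counted as inside. Planar (not geodesic) edges: neighborhood-scale
# polygons are small enough that planar containment is the standard choice.

ring_closed <- function(ring) {
  nrow(ring) >= 4L && all(ring[1L, ] == ring[nrow(ring), ])
}

close_ring <- function(ring) {
  if (ring_closed(ring)) ring else rbind(ring, ring[1L, , drop = FALSE])
}

rings_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1L]))
  ys <- unlist(lapply(rings, function(r) r[, 2L]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# exact test for a point lying on segment (x1,y1)-(x2,y2)
on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

point_on_boundary <- function(lon, lat, rings) {
  for (ring in rings) {
    n <- nrow(ring)
    for (i in seq_len(n - 1L)) {
      if (on_segment(lon, lat, ring[i, 1L], ring[i, 2L],
                     ring[i + 1L, 1L], ring[i + 1L, 2L])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd (ray crossing) over all rings, so interior rings act as holes.
# Boundary points are inside by convention.
point_in_polygon <- function(lon, lat, rings) {
  if (point_on_boundary(lon, lat, rings)) return(TRUE)
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    x <- ring[, 1L]; y <- ring[, 2L]
    j <- n - 1L  # rings are closed; last vertex repeats the first
    for (i in seq_len(n - 1L)) {
      if ((y[i] > lat) != (y[j] > lat)) {
        x_int <- x[i] + (lat - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
        if (lon < x_int) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  (crossings %% 2L) == 1L
}

polygon_area <- function(rings) {
  # signed shoelace sum: with GeoJSON orientations (exteriors CCW, holes CW)
  # holes subtract and multi-part geometries add
  abs(sum(vapply(rings, shoelace, numeric(1))))
}

shoelace <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}
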