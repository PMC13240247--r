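# Low-level planar geometry on bare coordinate matrices.
# All coordinates are in a projected equal-area system, units of meters;
# nothing here is geodesic.

# Squared distance from points (px, py) to segment (ax, ay)-(bx, by).
# Vectorized over points; degenerate (zero-length) segments collapse to points.
.pt_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    return((px - ax)^2 + (py - ay)^2)
  }
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx
  qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

# Minimum distance from points to a polyline given as an n x 2 matrix.
.dist_to_polyline <- function(px, py, coords) {
  n <- nrow(coords)
  if (n == 1L) {
    return(sqrt((px - coords[1, 1])^2 + (py - coords[1, 2])^2))
  }
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    d2 <- pmin(d2, .pt_seg_dist2(
      px, py,
      coords[i, 1], coords[i, 2], coords[i + 1L, 1], coords[i + 1L, 2]
    ))
  }
  sqrt(d2)
}

# Even-odd (ray casting) point-in-polygon test, vectorized over points.
# `coords` is a closed or open ring; the closing edge is implied.
# Points exactly on an edge may fall either way; callers that care use a
# distance test as well.
.point_in_poly <- function(px, py, coords) {
  n <- nrow(coords)
  if (n >= 2L && all(coords[1, ] == coords[n, ])) {
    coords <- coords[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Signed shoelace area of a ring (positive for counter-clockwise).
.ring_area <- function(coords) {
  n <- nrow(coords)
  if (n >= 2L && all(coords[1, ] == coords[n, ])) {
    coords <- coords[-n, , drop = FALSE]
    n <- n - 1L
  }
  x <- coords[, 1]
  y <- coords[, 2]
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Proper-intersection test between two segments (shared endpoints of
# consecutive ring edges do not count). Used to flag self-intersecting rings.
.segs_properly_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1)
  d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3)
  d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

.ring_self_intersects <- function(coords) {
  n <- nrow(coords)
  if (n >= 2L && all(coords[1, ] == coords[n, ])) {
    coords <- coords[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 4L) return(FALSE)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (i == 1L && j == n) next # adjacent via the closing edge
      if (.segs_properly_intersect(
        coords[i, ], coords[idx(i + 1L), ],
        coords[j, ], coords[idx(j + 1L), ]
      )) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Liang-Barsky clipping: length of segment (ax,ay)-(bx,by) inside the
# axis-aligned rectangle [x0,x1] x [y0,y1]. Returns 0 when disjoint.
.seg_length_in_rect <- function(ax, ay, bx, by, x0, x1, y0, y1) {
  dx <- bx - ax
  dy <- by - ay
  t0 <- 0
  t1 <- 1
  p <- c(-dx, dx, -dy, dy)
  q <- c(ax - x0, x1 - ax, ay - y0, y1 - ay)
  for (k in 1:4) {
    if (p[k] == 0) {
      if (q[k] < 0) return(0)
    } else {
      r <- q[k] / p[k]
      if (p[k] < 0) {
        if (r > t1) return(0)
        if (r > t0) t0 <- r
      } else {
        if (r < t0) return(0)
        if (r < t1) t1 <- r
      }
    }
  }
  (t1 - t0) * sqrt(dx * dx + dy * dy)
}
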