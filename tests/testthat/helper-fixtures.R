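# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small landscape shared by spatial tests (80 x 80 cells @ 250 m).
test_landscape <- function() {
  if (is.null(.fixture_env$landscape)) {
    .fixture_env$landscape <- generate_landscape(
      landscape_spec(extent_km = c(20, 20), resolution_m = 250, seed = 101)
    )
  }
  .fixture_env$landscape
}

# Axis-aligned square polygon feature.
square_feature <- function(x0, y0, side) {
  geom_polygon_feature(rbind(
    c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side)
  ))
}

# Square range polygon.
square_range <- function(x0, y0, side, name = "sq") {
  range_polygon(rbind(
    c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side)
  ), name = name)
}

# Small demographic model built in code: logit survival, log recruitment
# (calves per 100 cows), both declining with disturbance.
toy_model <- function(phi_S = 60, phi_R = 15) {
  demographic_model(
    survival = list(link = "logit", intercept = 2.2, coef_anthro = -0.02,
                    coef_fire = -0.005, precision = phi_S),
    recruitment = list(link = "log", intercept = 3.35, coef_anthro = -0.011,
                       coef_fire = -0.003, precision = phi_R)
  )
}

# Independent point-in-polygon oracle: winding number by signed-angle
# summation (different algorithm from the package's even-odd ray casting).
oracle_point_in_poly <- function(px, py, ring) {
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  vapply(seq_along(px), function(i) {
    total <- 0
    for (k in seq_len(n)) {
      a <- ring[k, ] - c(px[i], py[i])
      b <- ring[if (k == n) 1L else k + 1L, ] - c(px[i], py[i])
      ang <- atan2(a[1] * b[2] - a[2] * b[1], sum(a * b))
      total <- total + ang
    }
    abs(total) > pi # ~2*pi inside, ~0 outside
  }, TRUE)
}

# Independent segment-in-cell length oracle: cut the segment at every grid
# line crossing and assign each piece to the cell containing its midpoint.
oracle_cell_lengths <- function(coords, grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  res <- grid$resolution
  x0 <- grid$origin[1]
  y1 <- grid$origin[2]
  len <- matrix(0, nr, nc)
  for (s in seq_len(nrow(coords) - 1L)) {
    a <- coords[s, ]
    b <- coords[s + 1L, ]
    d <- b - a
    ts <- c(0, 1)
    if (d[1] != 0) {
      tx <- (x0 + (0:nc) * res - a[1]) / d[1]
      ts <- c(ts, tx[tx > 0 & tx < 1])
    }
    if (d[2] != 0) {
      ty <- (y1 - (0:nr) * res - a[2]) / d[2]
      ts <- c(ts, ty[ty > 0 & ty < 1])
    }
    ts <- sort(unique(ts))
    seg_len <- sqrt(sum(d^2))
    for (k in seq_len(length(ts) - 1L)) {
      mid <- a + (ts[k] + ts[k + 1L]) / 2 * d
      col <- floor((mid[1] - x0) / res) + 1L
      row <- floor((y1 - mid[2]) / res) + 1L
      if (col >= 1L && col <= nc && row >= 1L && row <= nr) {
        len[row, col] <- len[row, col] + (ts[k + 1L] - ts[k]) * seg_len
      }
    }
  }
  len
}

# Random simple (star-shaped) polygon around a center, for rasterization
# property tests. Jittered equally-spaced angles keep every angular gap
# below pi, which guarantees the ring is simple.
random_star_polygon <- function(cx, cy, rmin, rmax, n = 8L) {
  theta <- 2 * pi * (seq_len(n) - 1 + 0.8 * stats::runif(n)) / n
  r <- stats::runif(n, rmin, rmax)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}
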