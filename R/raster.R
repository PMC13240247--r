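#' Create a raster grid
#'
#' A minimal in-memory raster: a numeric, integer, or logical matrix on a
#' regular grid in a projected equal-area coordinate system. Row 1 is the
#' northernmost row; `origin` is the upper-left *corner* of the grid. All
#' area computations in the package exclude `nodata` cells.
#'
#' @param values Matrix of cell values (row 1 = top).
#' @param resolution Cell edge length in meters (> 0).
#' @param origin Numeric length-2, `(x, y)` of the upper-left corner.
#' @param nodata Logical matrix marking missing cells, same shape as
#'   `values`; defaults to `is.na(values)`.
#' @param crs Label of the projected coordinate reference system. Only used
#'   to guard against mixing layers from different projections; no
#'   reprojection is performed.
#' @return An object of class `caribou_grid`.
#' @export
raster_grid <- function(values, resolution, origin = c(0, 0), nodata = NULL,
                        crs = "local-aea") {
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0,
            length(origin) == 2L)
  if (is.null(nodata)) nodata <- is.na(values)
  if (!identical(dim(values), dim(nodata))) {
    stop("`values` and `nodata` must have identical dimensions", call. = FALSE)
  }
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin), nodata = nodata, crs = crs),
    class = "caribou_grid"
  )
}

#' @export
print.caribou_grid <- function(x, ...) {
  cat(sprintf(
    "<caribou_grid> %d x %d cells @ %g m, origin (%g, %g), crs %s\n",
    nrow(x$values), ncol(x$values), x$resolution,
    x$origin[1], x$origin[2], x$crs
  ))
  invisible(x)
}

#' @export
dim.caribou_grid <- function(x) dim(x$values)

# x-coordinates of column centers and y-coordinates of row centers.
grid_col_x <- function(grid) {
  grid$origin[1] + (seq_len(ncol(grid$values)) - 0.5) * grid$resolution
}
grid_row_y <- function(grid) {
  grid$origin[2] - (seq_len(nrow(grid$values)) - 0.5) * grid$resolution
}

# All cell centers as vectors in matrix (column-major) order.
grid_centers <- function(grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  list(
    x = rep(grid_col_x(grid), each = nr),
    y = rep(grid_row_y(grid), times = nc)
  )
}

#' Build an analysis grid covering a range polygon
#'
#' @param range A [range_polygon()].
#' @param resolution Cell size in meters (default 250 m, so that a 500 m
#'   buffer spans at least two cells).
#' @param pad Extra margin in meters around the range bounding box.
#' @return A `caribou_grid` of zeros covering the padded bounding box.
#' @export
grid_for_range <- function(range, resolution = 250, pad = 0) {
  stopifnot(inherits(range, "caribou_range"))
  xs <- range$boundary[, 1]
  ys <- range$boundary[, 2]
  xmin <- min(xs) - pad
  xmax <- max(xs) + pad
  ymin <- min(ys) - pad
  ymax <- max(ys) + pad
  nc <- max(1L, ceiling((xmax - xmin) / resolution))
  nr <- max(1L, ceiling((ymax - ymin) / resolution))
  raster_grid(matrix(0, nr, nc), resolution, origin = c(xmin, ymax),
              crs = range$crs)
}

#' Rasterize features onto a grid
#'
#' Cell-membership rule: a cell is marked `TRUE` when its center falls inside
#' a (possibly dilated) polygon, or lies within `max(buffer, half cell
#' diagonal)` of a line or point feature. The half-diagonal floor makes thin
#' lines register on coarse grids and keeps the footprint monotone in the
#' buffer width. An empty feature set yields an all-`FALSE` raster.
#'
#' @param features A [feature_set()].
#' @param grid A [raster_grid()] template (values ignored).
#' @return A logical `caribou_grid`.
#' @export
rasterize_features <- function(features, grid) {
  stopifnot(inherits(features, "caribou_features"), inherits(grid, "caribou_grid"))
  if (!identical(attr(features, "crs"), grid$crs)) {
    stop("coordinate reference mismatch between features (", attr(features, "crs"),
         ") and grid (", grid$crs, ")", call. = FALSE)
  }
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  out <- rep(FALSE, nr * nc)
  if (nrow(features) > 0L) {
    ctr <- grid_centers(grid)
    halfdiag <- grid$resolution * sqrt(2) / 2
    for (g in features$geometry) {
      hit <- switch(g$type,
        polygon = {
          inside <- .point_in_poly(ctr$x, ctr$y, g$coords)
          if (g$buffer_m > 0) {
            ring <- g$coords
            if (!all(ring[1, ] == ring[nrow(ring), ])) {
              ring <- rbind(ring, ring[1, ])
            }
            inside | .dist_to_polyline(ctr$x, ctr$y, ring) <= g$buffer_m
          } else {
            inside
          }
        },
        line = .dist_to_polyline(ctr$x, ctr$y, g$coords) <=
          max(g$buffer_m, halfdiag),
        point = .dist_to_polyline(ctr$x, ctr$y, g$coords) <=
          max(g$buffer_m, halfdiag),
        stop("unknown geometry type: ", g$type, call. = FALSE)
      )
      out <- out | hit
    }
  }
  raster_grid(matrix(out, nr, nc), grid$resolution, grid$origin,
              nodata = grid$nodata, crs = grid$crs)
}

#' Percent of a range covered by a boolean mask
#'
#' `100 * (TRUE cells with center inside the range) / (valid cells with
#' center inside the range)`, where valid means not `nodata`.
#'
#' @param mask Logical `caribou_grid`.
#' @param range A [range_polygon()].
#' @return A percentage in `[0, 100]`.
#' @export
area_fraction <- function(mask, range) {
  stopifnot(inherits(mask, "caribou_grid"), inherits(range, "caribou_range"))
  if (!identical(range$crs, mask$crs)) {
    stop("coordinate reference mismatch between mask and range", call. = FALSE)
  }
  ctr <- grid_centers(mask)
  in_range <- .point_in_poly(ctr$x, ctr$y, range$boundary)
  valid <- in_range & !as.vector(mask$nodata)
  n_valid <- sum(valid)
  if (n_valid == 0L) {
    stop("range contains no valid grid cells (outside grid, or all nodata)",
         call. = FALSE)
  }
  100 * sum(as.vector(mask$values)[valid]) / n_valid
}

# --- moving-window machinery (FFT convolution, nodata-aware) ----------------

# Zero-padded linear 2D convolution of matrix x with kernel k, returning the
# central part the same size as x. Real output; small FFT imaginary residue
# is discarded.
.conv2_same <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  pad <- function(m) {
    out <- matrix(0, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  full <- Re(stats::fft(stats::fft(pad(x)) * stats::fft(pad(k)), inverse = TRUE)) /
    (nr * nc)
  r0 <- (nrow(k) - 1L) %/% 2L
  c0 <- (ncol(k) - 1L) %/% 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

# Circular binary kernel of the given radius (in meters) on the grid's
# resolution; includes cells whose center offset is within the radius.
.circular_kernel <- function(radius, resolution) {
  ncell <- floor(radius / resolution)
  off <- (-ncell:ncell) * resolution
  k <- outer(off, off, function(dy, dx) as.numeric(dx^2 + dy^2 <= radius^2))
  k
}

# Moving-window mean of `grid` values over a circular window; nodata cells
# are excluded from both numerator and denominator. Cells whose window holds
# no valid neighbour become nodata.
window_mean <- function(grid, radius) {
  k <- .circular_kernel(radius, grid$resolution)
  v <- grid$values
  v[grid$nodata] <- 0
  w <- matrix(as.numeric(!grid$nodata), nrow(v), ncol(v))
  num <- .conv2_same(v, k)
  den <- .conv2_same(w, k)
  out <- num / den
  bad <- den < 0.5
  out[bad] <- NA_real_
  raster_grid(out, grid$resolution, grid$origin,
              nodata = bad | grid$nodata, crs = grid$crs)
}

# Moving-window sum (same window), treating nodata as zero.
window_sum <- function(grid, radius) {
  k <- .circular_kernel(radius, grid$resolution)
  v <- grid$values
  v[grid$nodata] <- 0
  raster_grid(.conv2_same(v, k), grid$resolution, grid$origin,
              nodata = grid$nodata, crs = grid$crs)
}

# Number of cells in the circular window (for converting sums to densities).
window_cell_count <- function(radius, resolution) sum(.circular_kernel(radius, resolution))

# --- raster text I/O (ESRI ASCII grid) --------------------------------------

#' Read / write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, northernmost row first.
#'
#' @param grid A `caribou_grid`.
#' @param path File path.
#' @param crs CRS label to attach on read.
#' @return `read_ascii_grid()` returns a `caribou_grid`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "caribou_grid"))
  v <- grid$values
  storage.mode(v) <- "numeric"
  v[grid$nodata] <- -9999
  nr <- nrow(v)
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nr),
    paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
    paste("yllcorner", format(grid$origin[2] - nr * grid$resolution,
                              scientific = FALSE)),
    paste("cellsize", format(grid$resolution, scientific = FALSE)),
    "NODATA_value -9999"
  )
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, crs = "local-aea") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[[`, "", 1L)
  val <- vapply(hdr, `[[`, "", 2L)
  h <- stats::setNames(as.numeric(val), tolower(key))
  v <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  nod <- v == h[["nodata_value"]]
  v[nod] <- NA_real_
  raster_grid(v, h[["cellsize"]],
              origin = c(h[["xllcorner"]],
                         h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]]),
              nodata = nod, crs = crs)
}
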