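#' Delineate a caribou range
#'
#' The boundary polygon of one local population (e.g., Missisa, James Bay,
#' Nipigon, Pagwachuan) — the unit over which disturbance footprints and
#' demographic covariates are assessed.
#'
#' @param coords An `n x 2` matrix of boundary vertices in projected
#'   equal-area meters; the ring is closed automatically and must enclose a
#'   positive area.
#' @param name Range label.
#' @param crs CRS label.
#' @return An object of class `caribou_range`.
#' @export
range_polygon <- function(coords, name = "range", crs = "local-aea") {
  coords <- unname(as.matrix(coords))
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 3L)
  if (!all(coords[1, ] == coords[nrow(coords), ])) {
    coords <- rbind(coords, coords[1, ])
  }
  if (abs(.ring_area(coords)) <= 0) {
    stop("range boundary encloses no area", call. = FALSE)
  }
  structure(list(boundary = coords, name = name, crs = crs),
            class = "caribou_range")
}

#' @export
print.caribou_range <- function(x, ...) {
  cat(sprintf("<caribou_range> %s: %d vertices, area %.1f km^2\n",
              x$name, nrow(x$boundary) - 1L,
              abs(.ring_area(x$boundary)) / 1e6))
  invisible(x)
}

#' Area of a range in square kilometers
#' @param range A [range_polygon()].
#' @export
range_area_km2 <- function(range) {
  stopifnot(inherits(range, "caribou_range"))
  abs(.ring_area(range$boundary)) / 1e6
}
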