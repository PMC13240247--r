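#' Build a set of disturbance features
#'
#' A feature set is a tibble with one row per feature: a `geometry`
#' list-column (each element a point, line, or polygon with an attached
#' dilation radius `buffer_m`), a `feature_class` (`road`, `mine`, `fire`,
#' or `other_anthro`), and a `year` (required for fire features, which are
#' dated burns). Buffering is exact in vector space: [buffer_features()]
#' increments the dilation radius, and rasterization tests cell centers
#' against the dilated geometry, so no resolution artifact enters before
#' the final cell-membership step.
#'
#' @param geometry List of geometries from [geom_point()], [geom_line()],
#'   [geom_polygon_feature()].
#' @param feature_class Character vector, recycled to the number of
#'   geometries.
#' @param year Integer vector of burn years (`NA` for non-fire features).
#' @param crs CRS label; must match the grid at rasterization time.
#' @return A tibble of class `caribou_features`.
#' @export
feature_set <- function(geometry = list(), feature_class = character(),
                        year = NA_integer_, crs = "local-aea") {
  n <- length(geometry)
  fc <- rep_len(as.character(feature_class), if (n > 0) n else length(feature_class))
  yr <- rep_len(as.integer(year), max(n, 0L))
  if (n > 0L) {
    ok <- fc %in% c("road", "mine", "fire", "other_anthro")
    if (!all(ok)) {
      stop("unknown feature_class: ", paste(unique(fc[!ok]), collapse = ", "),
           call. = FALSE)
    }
    if (any(fc == "fire" & is.na(yr))) {
      stop("fire features must carry a burn year", call. = FALSE)
    }
  }
  out <- tibble::tibble(
    geometry = geometry,
    feature_class = if (n > 0) fc else character(),
    year = if (n > 0) yr else integer()
  )
  class(out) <- c("caribou_features", class(out))
  attr(out, "crs") <- crs
  out
}

#' Geometry constructors
#'
#' @param x,y Point coordinates in meters.
#' @param coords An `n x 2` coordinate matrix (line vertices or polygon
#'   ring; polygon rings are closed automatically).
#' @param buffer_m Dilation radius already applied to the geometry.
#' @return A geometry list usable in [feature_set()].
#' @export
geom_point <- function(x, y, buffer_m = 0) {
  list(type = "point", coords = cbind(x, y), buffer_m = buffer_m)
}

#' @rdname geom_point
#' @export
geom_line <- function(coords, buffer_m = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 2L)
  list(type = "line", coords = unname(coords), buffer_m = buffer_m)
}

#' @rdname geom_point
#' @export
geom_polygon_feature <- function(coords, buffer_m = 0) {
  coords <- unname(as.matrix(coords))
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 3L)
  if (!all(coords[1, ] == coords[nrow(coords), ])) {
    coords <- rbind(coords, coords[1, ])
  }
  if (.ring_self_intersects(coords)) {
    warning("self-intersecting polygon ring; using even-odd interior rule",
            call. = FALSE)
  }
  list(type = "polygon", coords = coords, buffer_m = buffer_m)
}

#' Dilate all features by a buffer width
#'
#' Minkowski dilation of every geometry by `width` meters. The footprint of
#' a buffered feature is the set of points within `width` of the original
#' geometry; feature classes and years are preserved. `width = 0` returns
#' the features unchanged.
#'
#' @param features A [feature_set()].
#' @param width Buffer width in meters, `>= 0`.
#' @return A `caribou_features` with dilated geometries.
#' @export
buffer_features <- function(features, width) {
  stopifnot(inherits(features, "caribou_features"))
  if (!is.numeric(width) || length(width) != 1L || is.na(width) || width < 0) {
    stop("`width` must be a single non-negative number of meters", call. = FALSE)
  }
  if (width == 0 || nrow(features) == 0L) return(features)
  features$geometry <- lapply(features$geometry, function(g) {
    g$buffer_m <- g$buffer_m + width
    g
  })
  features
}

#' Combine feature sets
#'
#' @param ... `caribou_features` objects sharing one CRS.
#' @return Their row-wise union.
#' @export
combine_features <- function(...) {
  fs <- list(...)
  crs <- unique(vapply(fs, function(f) attr(f, "crs"), ""))
  if (length(crs) > 1L) stop("cannot combine features from different CRS", call. = FALSE)
  out <- dplyr::bind_rows(lapply(fs, function(f) {
    class(f) <- setdiff(class(f), "caribou_features")
    f
  }))
  class(out) <- c("caribou_features", class(out))
  attr(out, "crs") <- crs
  out
}

#' Footprint area of a feature set
#'
#' Area of the union of (dilated) feature footprints, measured by cell
#' counting on a fine grid covering the features. Accuracy improves as
#' `resolution` shrinks relative to feature size.
#'
#' @param features A [feature_set()].
#' @param resolution Measurement cell size in meters.
#' @return Area in square meters.
#' @export
footprint_area <- function(features, resolution) {
  if (nrow(features) == 0L) return(0)
  xs <- unlist(lapply(features$geometry, function(g) g$coords[, 1]))
  ys <- unlist(lapply(features$geometry, function(g) g$coords[, 2]))
  pad <- max(vapply(features$geometry, function(g) g$buffer_m, 0)) +
    2 * resolution
  nc <- ceiling((max(xs) - min(xs) + 2 * pad) / resolution)
  nr <- ceiling((max(ys) - min(ys) + 2 * pad) / resolution)
  grid <- raster_grid(matrix(0, nr, nc), resolution,
                      origin = c(min(xs) - pad, max(ys) + pad),
                      crs = attr(features, "crs"))
  mask <- rasterize_features(features, grid)
  sum(mask$values) * resolution^2
}

# --- vector text I/O (GeoJSON) ----------------------------------------------

#' Read / write feature sets as GeoJSON
#'
#' Features are stored as a `FeatureCollection`; `feature_class`, `year`,
#' and the dilation radius `buffer_m` travel in each feature's properties.
#' Coordinates are written as-is (projected meters), with the CRS label in
#' the collection-level `crs_label` member.
#'
#' @param features A [feature_set()].
#' @param path File path.
#' @return `read_features_geojson()` returns a `caribou_features`;
#'   `write_features_geojson()` returns `path` invisibly.
#' @export
write_features_geojson <- function(features, path) {
  stopifnot(inherits(features, "caribou_features"))
  feats <- purrr::pmap(
    list(features$geometry, features$feature_class, features$year),
    function(g, fc, yr) {
      gj_type <- switch(g$type, point = "Point", line = "LineString",
                        polygon = "Polygon")
      coords <- switch(g$type,
        point = as.numeric(g$coords[1, ]),
        line = unname(split(g$coords, row(g$coords)[, 1])) |>
          lapply(as.numeric),
        polygon = list(unname(split(g$coords, row(g$coords)[, 1])) |>
          lapply(as.numeric))
      )
      props <- list(feature_class = fc, buffer_m = g$buffer_m)
      if (!is.na(yr)) props$year <- yr
      list(
        type = "Feature",
        geometry = list(type = gj_type, coordinates = coords),
        properties = props
      )
    }
  )
  obj <- list(type = "FeatureCollection",
              crs_label = attr(features, "crs"),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features_geojson
#' @export
read_features_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  crs <- obj$crs_label %||% "local-aea"
  geoms <- list()
  fc <- character()
  yr <- integer()
  for (f in obj$features) {
    gt <- f$geometry$type
    cc <- f$geometry$coordinates
    buf <- f$properties$buffer_m %||% 0
    g <- switch(gt,
      Point = geom_point(cc[[1]], cc[[2]], buffer_m = buf),
      LineString = geom_line(do.call(rbind, lapply(cc, unlist)), buffer_m = buf),
      Polygon = geom_polygon_feature(do.call(rbind, lapply(cc[[1]], unlist)),
                                     buffer_m = buf),
      stop("unsupported GeoJSON geometry: ", gt, call. = FALSE)
    )
    geoms <- c(geoms, list(g))
    fc <- c(fc, f$properties$feature_class)
    y <- f$properties$year
    yr <- c(yr, if (is.null(y) || length(y) == 0L) NA_integer_ else as.integer(y))
  }
  feature_set(geoms, fc, yr, crs = crs)
}
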