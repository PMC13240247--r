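#' Load seasonal RSF coefficient tables
#'
#' Reads a CSV with columns `range,season,predictor,coefficient,transform`
#' (one row per linear-predictor term). The package ships an illustrative
#' table at `system.file("extdata", "rsf_coefficients_illustrative.csv", package =
#' "caribouscen")` — synthetic values with the qualitative structure of
#' published boreal caribou coefficient tables; real applications should
#' transcribe the published values for their ranges.
#'
#' @param path CSV path.
#' @return A tibble of terms.
#' @export
read_rsf_coefficients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("range", "season", "predictor", "coefficient", "transform")
  if (!all(need %in% names(df))) {
    stop("coefficient CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Select one range-season coefficient table
#'
#' @param coefficients Tibble from [read_rsf_coefficients()], or any data
#'   frame with the same columns.
#' @param range_name Range label.
#' @param season One of `"spring"`, `"summer"`, `"fall"`, `"winter"`.
#' @return An object of class `rsf_table`.
#' @export
rsf_table <- function(coefficients, range_name, season) {
  season <- match.arg(season, c("spring", "summer", "fall", "winter"))
  rows <- dplyr::filter(tibble::as_tibble(coefficients),
                        .data$range == range_name, .data$season == !!season)
  if (nrow(rows) == 0L) {
    stop("no coefficients for range '", range_name, "', season '", season, "'",
         call. = FALSE)
  }
  if (anyDuplicated(rows$predictor)) {
    stop("duplicate predictor names in coefficient table", call. = FALSE)
  }
  transform <- unique(rows$transform)
  if (length(transform) != 1L || !transform %in% c("exponential", "logistic")) {
    stop("`transform` must be a single value: 'exponential' or 'logistic'",
         call. = FALSE)
  }
  structure(
    list(range_name = range_name, season = season,
         terms = stats::setNames(rows$coefficient, rows$predictor),
         transform = transform),
    class = "rsf_table"
  )
}

#' Derive RSF predictor rasters from a landscape and scenario
#'
#' Builds the habitat covariates the coefficient tables act on:
#' moving-window proportions of each land-cover class (circular window,
#' default 5 km radius), road density (km of road per km^2 of window), and
#' distance to the nearest road (km). Window statistics exclude nodata
#' cells; with no roads in the scenario, road density is zero everywhere
#' and distance to road is the landscape diagonal (an effectively-infinite
#' sentinel, documented rather than `Inf` so surfaces stay finite).
#'
#' @param landscape A [generate_landscape()] result (or a list with
#'   `landcover` grid carrying a `classes` attribute).
#' @param scenario Anthropogenic [feature_set()]; its `road` features feed
#'   the road predictors.
#' @param window_radius_m Moving-window radius in meters (default 5000).
#' @param predictors Character vector naming the layers to build; defaults
#'   to all proportions plus `road_density` and `dist_to_road`.
#' @return A named list of co-registered [raster_grid()]s, class
#'   `predictor_stack`.
#' @export
derive_predictors <- function(landscape, scenario,
                              window_radius_m = 5000,
                              predictors = NULL) {
  lc <- landscape$landcover
  classes <- attr(lc, "classes")
  default <- c(paste0("prop_", classes), "road_density", "dist_to_road")
  predictors <- predictors %||% default
  unknown <- setdiff(predictors, default)
  if (length(unknown) > 0L) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(default, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (i in seq_along(classes)) {
    nm <- paste0("prop_", classes[i])
    if (!nm %in% predictors) next
    ind <- raster_grid((lc$values == i) * 1, lc$resolution, lc$origin,
                       nodata = lc$nodata, crs = lc$crs)
    out[[nm]] <- window_mean(ind, window_radius_m)
  }
  roads <- scenario[scenario$feature_class == "road", , drop = FALSE]
  if ("road_density" %in% predictors) {
    len <- .road_length_raster(roads, lc)
    win <- window_sum(len, window_radius_m)
    area_m2 <- window_cell_count(window_radius_m, lc$resolution) *
      lc$resolution^2
    dens <- raster_grid(win$values / area_m2 * 1000, lc$resolution, lc$origin,
                        nodata = lc$nodata, crs = lc$crs) # km / km^2
    out[["road_density"]] <- dens
  }
  if ("dist_to_road" %in% predictors) {
    ctr <- grid_centers(lc)
    if (nrow(roads) == 0L) {
      d <- rep(sqrt(sum((dim(lc$values) * lc$resolution)^2)), length(ctr$x))
    } else {
      d <- rep(Inf, length(ctr$x))
      for (g in roads$geometry) {
        d <- pmin(d, .dist_to_polyline(ctr$x, ctr$y, g$coords))
      }
    }
    out[["dist_to_road"]] <- raster_grid(
      matrix(d / 1000, nrow(lc$values), ncol(lc$values)),
      lc$resolution, lc$origin, nodata = lc$nodata, crs = lc$crs
    )
  }
  structure(out[predictors[predictors %in% names(out)]],
            class = "predictor_stack")
}

# Exact per-cell road length (meters) by clipping every segment to every
# cell rectangle it can touch.
.road_length_raster <- function(roads, grid) {
  nr <- nrow(grid$values)
  nc <- ncol(grid$values)
  res <- grid$resolution
  x0 <- grid$origin[1]
  y1 <- grid$origin[2] # top
  len <- matrix(0, nr, nc)
  for (g in roads$geometry) {
    cc <- g$coords
    for (s in seq_len(nrow(cc) - 1L)) {
      ax <- cc[s, 1]; ay <- cc[s, 2]
      bx <- cc[s + 1L, 1]; by <- cc[s + 1L, 2]
      ci <- floor((c(ax, bx) - x0) / res)
      ri <- floor((y1 - c(ay, by)) / res)
      for (col in max(0L, min(ci)):min(nc - 1L, max(ci))) {
        for (row in max(0L, min(ri)):min(nr - 1L, max(ri))) {
          l <- .seg_length_in_rect(
            ax, ay, bx, by,
            x0 + col * res, x0 + (col + 1L) * res,
            y1 - (row + 1L) * res, y1 - row * res
          )
          if (l > 0) len[row + 1L, col + 1L] <- len[row + 1L, col + 1L] + l
        }
      }
    }
  }
  raster_grid(len, res, grid$origin, nodata = grid$nodata, crs = grid$crs)
}

#' Project an RSF surface
#'
#' Evaluates the linear predictor `eta = sum(beta_i * x_i)` cell-wise over
#' the predictor stack and maps it to a 0-1 relative-probability-of-use
#' surface: `w = exp(eta)` (the standard exponential RSF form) or
#' `w = plogis(eta)`, then rescaled by the maximum over valid cells so the
#' best cell scores 1. Cells missing any predictor become nodata.
#'
#' @param table An [rsf_table()].
#' @param predictors A [derive_predictors()] stack.
#' @return An object of class `rsf_surface`: the 0-1 [raster_grid()] plus
#'   `season` and `source_range`.
#' @export
apply_rsf <- function(table, predictors) {
  stopifnot(inherits(table, "rsf_table"))
  missing <- setdiff(names(table$terms), names(predictors))
  if (length(missing) > 0L) {
    stop("predictor stack is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  first <- predictors[[names(table$terms)[1]]]
  eta <- matrix(0, nrow(first$values), ncol(first$values))
  nodata <- matrix(FALSE, nrow(first$values), ncol(first$values))
  for (nm in names(table$terms)) {
    layer <- predictors[[nm]]
    nodata <- nodata | layer$nodata | is.na(layer$values)
    v <- layer$values
    v[is.na(v)] <- 0
    eta <- eta + table$terms[[nm]] * v
  }
  if (all(nodata)) stop("all cells are nodata", call. = FALSE)
  w <- if (table$transform == "exponential") {
    # subtract the max before exponentiating for numerical stability; the
    # max-rescale makes the surface invariant to constant shifts in eta
    exp(eta - max(eta[!nodata]))
  } else {
    stats::plogis(eta)
  }
  w[nodata] <- NA_real_
  w <- w / max(w, na.rm = TRUE)
  structure(
    list(values = raster_grid(w, first$resolution, first$origin,
                              nodata = nodata, crs = first$crs),
         season = table$season, source_range = table$range_name),
    class = "rsf_surface"
  )
}

#' @export
print.rsf_surface <- function(x, ...) {
  cat(sprintf("<rsf_surface> %s / %s: %d x %d cells, range of use [%.3f, 1]\n",
              x$source_range, x$season,
              nrow(x$values$values), ncol(x$values$values),
              min(x$values$values, na.rm = TRUE)))
  invisible(x)
}

#' Cross-range transferability of RSF surfaces
#'
#' Pairs the cell values of a reference surface (e.g., the range's own
#' model) with a surface transferred from an adjacent range on the same
#' grid, and reports their Pearson correlation over the cells valid in
#' both. The paired values support the scatterplot diagnostic of
#' transferability.
#'
#' @param reference,transferred [apply_rsf()] surfaces on one grid and
#'   season.
#' @param thin_n Optional cap on the number of pairs kept for plotting
#'   (sampled with `seed`); the correlation always uses all pairs.
#' @param seed Seed for thinning.
#' @return An object of class `transferability_report`: `pearson_r`,
#'   `n_cells`, `degenerate` (TRUE when either surface has zero variance,
#'   in which case `pearson_r` is `NA`), `pairs` tibble, `season`,
#'   `reference_range`, `transferred_range`.
#' @export
compare_surfaces <- function(reference, transferred, thin_n = NULL, seed = 42) {
  stopifnot(inherits(reference, "rsf_surface"),
            inherits(transferred, "rsf_surface"))
  a <- reference$values
  b <- transferred$values
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$origin, b$origin)) || a$resolution != b$resolution) {
    stop("surfaces are not on the same grid", call. = FALSE)
  }
  valid <- !a$nodata & !b$nodata & !is.na(a$values) & !is.na(b$values)
  n <- sum(valid)
  if (n < 3L) stop("fewer than 3 shared valid cells", call. = FALSE)
  x <- a$values[valid]
  y <- b$values[valid]
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  r <- if (degenerate) {
    warning("zero-variance surface: correlation undefined", call. = FALSE)
    NA_real_
  } else {
    stats::cor(x, y)
  }
  pairs <- tibble::tibble(reference = x, transferred = y)
  if (!is.null(thin_n) && thin_n < n) {
    pairs <- local_seed(seed, pairs[sample(n, thin_n), ])
  }
  structure(
    list(pearson_r = r, n_cells = n, degenerate = degenerate, pairs = pairs,
         season = reference$season,
         reference_range = reference$source_range,
         transferred_range = transferred$source_range),
    class = "transferability_report"
  )
}

#' @export
print.transferability_report <- function(x, ...) {
  cat(sprintf("<transferability_report> %s: %s vs %s, r = %s over %d cells\n",
              x$season, x$reference_range, x$transferred_range,
              if (is.na(x$pearson_r)) "NA (degenerate)" else
                sprintf("%.3f", x$pearson_r), x$n_cells))
  invisible(x)
}

#' @rdname tidy.caribou_ensemble
#' @export
tidy.transferability_report <- function(x, ...) x$pairs

#' @rdname tidy.caribou_ensemble
#' @export
glance.transferability_report <- function(x, ...) {
  tibble::tibble(season = x$season, reference_range = x$reference_range,
                 transferred_range = x$transferred_range,
                 pearson_r = x$pearson_r, n_cells = x$n_cells,
                 degenerate = x$degenerate)
}
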