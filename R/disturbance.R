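#' Summarize disturbance footprints over a range
#'
#' Computes the four standard range-level disturbance percentages used as
#' demographic covariates: the anthropogenic footprint (all human features
#' dilated by `buffer_width`, default 500 m), recent wildfire
#' (burns within `fire_horizon` years of `reference_year`, *not* buffered —
#' only anthropogenic disturbance is buffered), their union, and fire
#' outside the anthropogenic footprint. By set algebra the union satisfies
#' `pct_total = pct_anthro + pct_fire_excl_anthro` exactly.
#'
#' @param anthro Anthropogenic [feature_set()] (roads, mines, ...).
#' @param fire Fire [feature_set()]; every feature needs a burn `year`.
#' @param range A [range_polygon()].
#' @param buffer_width Anthropogenic buffer in meters (default 500).
#' @param fire_horizon Fire look-back window in years (default 40).
#' @param reference_year Year against which fire ages are measured.
#' @param resolution Analysis cell size in meters (default 250).
#' @param grid Optional precomputed grid; defaults to
#'   [grid_for_range()] at `resolution`.
#' @return A one-row tibble of class `disturbance_summary` with columns
#'   `pct_anthro`, `pct_fire`, `pct_total`, `pct_fire_excl_anthro`.
#' @export
summarize_disturbance <- function(anthro, fire, range,
                                  buffer_width = 500, fire_horizon = 40,
                                  reference_year,
                                  resolution = 250, grid = NULL) {
  stopifnot(inherits(anthro, "caribou_features"),
            inherits(fire, "caribou_features"),
            inherits(range, "caribou_range"))
  if (nrow(fire) > 0L) {
    if (anyNA(fire$year)) stop("fire features are missing burn years", call. = FALSE)
    if (missing(reference_year)) {
      stop("`reference_year` is required when fire features are present",
           call. = FALSE)
    }
    if (any(fire$year > reference_year)) {
      stop("fire years later than `reference_year`", call. = FALSE)
    }
  }
  if (missing(reference_year)) reference_year <- NA_integer_
  if (is.null(grid)) grid <- grid_for_range(range, resolution = resolution)

  anthro_mask <- rasterize_features(buffer_features(anthro, buffer_width), grid)
  recent <- if (nrow(fire) > 0L) {
    fire[(reference_year - fire$year) <= fire_horizon, , drop = FALSE]
  } else {
    fire
  }
  fire_mask <- rasterize_features(recent, grid)

  ctr <- grid_centers(grid)
  in_range <- .point_in_poly(ctr$x, ctr$y, range$boundary)
  valid <- in_range & !as.vector(grid$nodata)
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("range contains no valid grid cells", call. = FALSE)

  a <- as.vector(anthro_mask$values)[valid]
  f <- as.vector(fire_mask$values)[valid]
  out <- tibble::tibble(
    pct_anthro = 100 * sum(a) / n_valid,
    pct_fire = 100 * sum(f) / n_valid,
    pct_total = 100 * sum(a | f) / n_valid,
    pct_fire_excl_anthro = 100 * sum(f & !a) / n_valid
  )
  class(out) <- c("disturbance_summary", class(out))
  out
}

#' Disturbance table across scenarios
#'
#' One [summarize_disturbance()] row per land-use scenario, with identical
#' fire inputs across rows, so only the anthropogenic footprint varies.
#'
#' @param scenarios Named list of anthropogenic [feature_set()]s (names are
#'   scenario labels) or a list of `list(label =, features =)` pairs.
#' @param fire Fire [feature_set()] shared by all scenarios.
#' @param range A [range_polygon()].
#' @param ... Passed to [summarize_disturbance()] (`buffer_width`,
#'   `fire_horizon`, `reference_year`, `resolution`, `grid`).
#' @return A tibble with a leading `scenario` column, one row per scenario.
#' @export
scenario_table <- function(scenarios, fire, range, ...) {
  stopifnot(length(scenarios) >= 1L)
  labels <- names(scenarios)
  if (is.null(labels) || any(labels == "")) {
    stop("`scenarios` must be a named list of feature sets", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate scenario labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  args <- list(...)
  if (is.null(args$grid)) {
    # one shared grid so every row is measured on the same cells
    args$grid <- grid_for_range(range, resolution = args$resolution %||% 250)
    args$resolution <- NULL
  }
  rows <- purrr::map(scenarios, function(fs) {
    do.call(summarize_disturbance,
            c(list(anthro = fs, fire = fire, range = range), args))
  })
  dplyr::bind_cols(
    tibble::tibble(scenario = labels),
    dplyr::bind_rows(lapply(rows, function(r) {
      class(r) <- setdiff(class(r), "disturbance_summary")
      r
    }))
  )
}

#' Write a scenario disturbance table as CSV
#'
#' Columns `scenario, pct_anthro, pct_fire, pct_total, pct_fire_excl_anthro`;
#' percentages are rounded to 2 decimals in the file (full precision is kept
#' in the returned tibble).
#'
#' @param tbl Output of [scenario_table()].
#' @param path Output CSV path.
#' @export
write_disturbance_csv <- function(tbl, path) {
  out <- dplyr::mutate(tbl, dplyr::across(dplyr::starts_with("pct_"),
                                          ~ round(.x, 2)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
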