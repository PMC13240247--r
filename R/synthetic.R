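#' Specify a synthetic landscape
#'
#' Describes a seeded artificial caribou range used to exercise the full
#' workflow without external GIS data: a categorical land-cover raster with
#' spatially autocorrelated patches, a patchy burn history with ages, and an
#' irregular range boundary. The generator emulates the *structure* of a
#' boreal range (sparse linear features, polygonal claims, dated fires), not
#' its ecology.
#'
#' @param extent_km Width and height of the landscape in kilometers.
#' @param resolution_m Cell size in meters.
#' @param landcover_classes Named numeric vector of target class
#'   proportions; must sum to 1 (within 1e-9).
#' @param fire_fraction Target fraction of the range burned within
#'   `fire_age_range` (0-1).
#' @param fire_age_range Two integers, youngest and oldest burn age in
#'   years at `reference_year`.
#' @param reference_year Calendar year fire ages are measured against.
#' @param seed Integer seed; identical specs and seeds give bit-identical
#'   landscapes.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent_km = c(40, 40), resolution_m = 250,
                           landcover_classes = c(conifer = 0.45, peatland = 0.35,
                                                 mixedwood = 0.15, water = 0.05),
                           fire_fraction = 0.05,
                           fire_age_range = c(1, 60),
                           reference_year = 2020,
                           seed = 42) {
  stopifnot(length(extent_km) == 2L, length(fire_age_range) == 2L)
  if (any(extent_km <= 0) || resolution_m <= 0) {
    stop("extent and resolution must be positive", call. = FALSE)
  }
  if (abs(sum(landcover_classes) - 1) > 1e-9) {
    stop("land-cover class proportions must sum to 1", call. = FALSE)
  }
  if (fire_fraction < 0 || fire_fraction > 1) {
    stop("`fire_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(extent_km = extent_km, resolution_m = resolution_m,
         landcover_classes = landcover_classes,
         fire_fraction = fire_fraction,
         fire_age_range = sort(as.integer(fire_age_range)),
         reference_year = as.integer(reference_year),
         seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

# Gaussian-smoothed white noise: the patch-generating field.
.smooth_noise <- function(nr, nc, sigma_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * sigma_cells))
  off <- -half:half
  k <- outer(off, off, function(dy, dx) exp(-(dx^2 + dy^2) / (2 * sigma_cells^2)))
  k <- k / sum(k)
  .conv2_same(z, k)
}

# Irregular closed ring: circle of radius r0 around (cx, cy) modulated by a
# few random low-order harmonics.
.blob_ring <- function(cx, cy, r0, n_vertices = 36, roughness = 0.15) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  mod <- rep(0, n_vertices)
  for (h in 1:3) {
    mod <- mod + stats::rnorm(1, sd = roughness / h) * cos(h * theta) +
      stats::rnorm(1, sd = roughness / h) * sin(h * theta)
  }
  r <- r0 * pmax(0.3, 1 + mod)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Generate a synthetic landscape
#'
#' @param spec A [landscape_spec()].
#' @return A list of class `caribou_landscape` with elements `landcover`
#'   (integer [raster_grid()] with a `classes` attribute), `fire`
#'   ([feature_set()] of dated burn polygons), `range` ([range_polygon()]),
#'   and `spec`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  local_seed(spec$seed, {
    w <- spec$extent_km[1] * 1000
    h <- spec$extent_km[2] * 1000
    res <- spec$resolution_m
    nc <- ceiling(w / res)
    nr <- ceiling(h / res)

    # categorical cover by slicing one autocorrelated field at the
    # empirical quantiles of the target proportions
    field <- .smooth_noise(nr, nc, sigma_cells = 6)
    probs <- cumsum(spec$landcover_classes)
    cuts <- stats::quantile(field, probs = probs[-length(probs)], names = FALSE)
    cover <- matrix(findInterval(field, cuts) + 1L, nr, nc)
    landcover <- raster_grid(cover, res, origin = c(0, h))
    attr(landcover, "classes") <- names(spec$landcover_classes)

    range <- range_polygon(
      .blob_ring(w / 2, h / 2, r0 = 0.42 * min(w, h), n_vertices = 48),
      name = "synthetic"
    )
    range_area <- abs(.ring_area(range$boundary))

    # dated burn polygons; blob areas accumulate to the target burned
    # fraction (overlap between burns is possible but rare and harmless)
    fires <- list()
    years <- integer()
    target <- spec$fire_fraction * range_area
    burned <- 0
    while (burned < target && length(fires) < 500L) {
      repeat {
        cx <- stats::runif(1, 0, w)
        cy <- stats::runif(1, 0, h)
        if (.point_in_poly(cx, cy, range$boundary)) break
      }
      r0 <- stats::runif(1, 0.02, 0.06) * min(w, h)
      ring <- .blob_ring(cx, cy, r0, n_vertices = 24, roughness = 0.2)
      g <- geom_polygon_feature(ring)
      fires <- c(fires, list(g))
      years <- c(years, spec$reference_year -
                   sample(seq(spec$fire_age_range[1], spec$fire_age_range[2]), 1L))
      burned <- burned + abs(.ring_area(ring))
    }
    fire <- feature_set(fires, rep("fire", length(fires)), years)

    structure(list(landcover = landcover, fire = fire, range = range,
                   spec = spec),
              class = "caribou_landscape")
  })
}

#' @export
print.caribou_landscape <- function(x, ...) {
  cat(sprintf("<caribou_landscape> %d x %d cells @ %g m, %d burn polygons\n",
              nrow(x$landcover$values), ncol(x$landcover$values),
              x$landcover$resolution, nrow(x$fire)))
  invisible(x)
}

# --- scenario machinery ------------------------------------------------------

#' Specify a land-use scenario
#'
#' Scenarios are nested by construction: `roads_only` extends the `base`
#' road network, and `roads_and_mines` adds mining-claim polygons on top of
#' the `roads_only` network, mirroring staged development proposals.
#'
#' @param name Scenario label.
#' @param road_length_km Total road length in the scenario.
#' @param mine_fraction Target fraction (0-1) of the range area in
#'   mining-claim polygons (unbuffered).
#' @param seed Integer seed for feature placement.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, road_length_km = 0, mine_fraction = 0,
                          seed = 42) {
  if (mine_fraction < 0 || mine_fraction > 1) {
    stop("`mine_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (road_length_km < 0) stop("`road_length_km` must be >= 0", call. = FALSE)
  structure(list(name = name, road_length_km = road_length_km,
                 mine_fraction = mine_fraction, seed = as.integer(seed)),
            class = "scenario_spec")
}

# Length of a polyline.
.polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums((coords[-1, , drop = FALSE] -
                      coords[-nrow(coords), , drop = FALSE])^2)))
}

# Prefix of a polyline with total length L (interpolating the last vertex).
.polyline_prefix <- function(coords, L) {
  if (L <= 0) return(NULL)
  seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                         coords[-nrow(coords), , drop = FALSE])^2))
  cum <- cumsum(seg)
  if (L >= cum[length(cum)]) return(coords)
  i <- which(cum >= L)[1]
  prev <- if (i == 1L) 0 else cum[i - 1L]
  t <- (L - prev) / seg[i]
  end <- coords[i, ] + t * (coords[i + 1L, ] - coords[i, ])
  rbind(coords[seq_len(i), , drop = FALSE], end)
}

# Pool of candidate roads crossing the landscape west-east at staggered
# latitudes with smooth meanders, plus the sequence of candidate mine blobs
# strung along the first roads. Deterministic given the seed.
.scenario_pool <- function(landscape, seed, n_roads = 14L, n_mines = 80L) {
  spec <- landscape$spec
  w <- spec$extent_km[1] * 1000
  h <- spec$extent_km[2] * 1000
  local_seed(seed, {
    roads <- vector("list", n_roads)
    ys <- h * (0.5 + 0.8 * (stats::runif(n_roads) - 0.5))
    for (i in seq_len(n_roads)) {
      x <- seq(-0.05 * w, 1.05 * w, length.out = 25L)
      wiggle <- cumsum(stats::rnorm(length(x), sd = h * 0.01))
      wiggle <- wiggle - seq(wiggle[1], wiggle[length(wiggle)],
                             length.out = length(wiggle))
      roads[[i]] <- cbind(x, ys[i] + wiggle)
    }
    road_lengths <- vapply(roads, .polyline_length, 0)

    # mine blobs centred on road vertices that fall inside the range
    anchors <- do.call(rbind, roads)
    keep <- .point_in_poly(anchors[, 1], anchors[, 2], landscape$range$boundary)
    anchors <- anchors[keep, , drop = FALSE]
    anchors <- anchors[sample(nrow(anchors), min(n_mines, nrow(anchors))), ,
                       drop = FALSE]
    mines <- lapply(seq_len(nrow(anchors)), function(i) {
      r0 <- stats::runif(1, 0.01, 0.03) * min(w, h)
      .blob_ring(anchors[i, 1], anchors[i, 2], r0, n_vertices = 16,
                 roughness = 0.2)
    })
    list(roads = roads, road_lengths = road_lengths, mines = mines)
  })
}

# Assemble the anthropogenic feature set for a road-length prefix (meters),
# a mine linear-size multiplier, and a continuous mine budget (number of
# mine blobs; a fractional part shrinks the last blob, so the buffered
# footprint responds near-continuously to the budget).
.assemble_scenario <- function(pool, road_m, mine_scale, mine_budget) {
  geoms <- list()
  classes <- character()
  remaining <- road_m
  for (i in seq_along(pool$roads)) {
    if (remaining <= 0) break
    take <- min(remaining, pool$road_lengths[i])
    pref <- .polyline_prefix(pool$roads[[i]], take)
    if (!is.null(pref) && nrow(pref) >= 2L) {
      geoms <- c(geoms, list(geom_line(pref)))
      classes <- c(classes, "road")
    }
    remaining <- remaining - take
  }
  if (mine_scale > 0 && mine_budget > 0) {
    n_full <- min(floor(mine_budget), length(pool$mines))
    frac <- if (n_full < length(pool$mines)) mine_budget - n_full else 0
    scales <- c(rep(mine_scale, n_full),
                if (frac > 0) frac * mine_scale)
    for (k in seq_along(scales)) {
      ring <- pool$mines[[k]]
      c0 <- colMeans(ring[-nrow(ring), , drop = FALSE])
      scaled <- sweep(sweep(ring, 2, c0) * scales[k], 2, c0, `+`)
      geoms <- c(geoms, list(geom_polygon_feature(scaled)))
      classes <- c(classes, "mine")
    }
  }
  feature_set(geoms, classes)
}

#' Generate nested disturbance scenarios
#'
#' Draws road polylines crossing the range and mining-claim polygon clusters
#' anchored on the roads, one nested feature set per scenario spec. Within a
#' shared seed the scenarios draw from one feature pool, so a longer road
#' network geometrically contains the shorter one and buffered disturbance
#' is non-decreasing along the nesting.
#'
#' @param landscape A [generate_landscape()] result.
#' @param specs List of [scenario_spec()]s, ordered base -> roads_only ->
#'   roads_and_mines (road lengths and mine fractions must be
#'   non-decreasing).
#' @return Named list of [feature_set()]s.
#' @export
generate_scenarios <- function(landscape, specs) {
  stopifnot(inherits(landscape, "caribou_landscape"), length(specs) >= 1L)
  lens <- vapply(specs, function(s) s$road_length_km, 0)
  mfr <- vapply(specs, function(s) s$mine_fraction, 0)
  if (is.unsorted(lens) || is.unsorted(mfr)) {
    stop("scenario specs must be nested: road lengths and mine fractions non-decreasing",
         call. = FALSE)
  }
  if (max(mfr) > 0.5) {
    stop("mine_fraction above 0.5 cannot be placed in the range", call. = FALSE)
  }
  pool <- .scenario_pool(landscape, specs[[1]]$seed)
  range_area <- abs(.ring_area(landscape$range$boundary))
  base_mine_area <- sum(vapply(pool$mines, function(r) abs(.ring_area(r)), 0))
  out <- lapply(specs, function(s) {
    mine_scale <- if (s$mine_fraction > 0) {
      sqrt(s$mine_fraction * range_area / base_mine_area)
    } else {
      0
    }
    .assemble_scenario(pool, s$road_length_km * 1000, mine_scale,
                       mine_budget = length(pool$mines))
  })
  stats::setNames(out, vapply(specs, function(s) s$name, ""))
}

#' Calibrate scenarios to target disturbance percentages
#'
#' Finds, by bisection, the road length (and then mine size) whose buffered
#' anthropogenic footprint matches each target percentage of the range, to a
#' stated tolerance. Targets must be non-decreasing (nested scenarios).
#'
#' @param landscape A [generate_landscape()] result.
#' @param targets Named numeric vector of target buffered-anthropogenic
#'   percentages (0-100), in nesting order; e.g.
#'   `c(base = 0.41, roads_only = 1.11, roads_and_mines = 16.91)`.
#' @param buffer_width Anthropogenic buffer in meters (default 500).
#' @param resolution Measurement cell size in meters.
#' @param tol Calibration tolerance in percentage points (default 0.5).
#' @param seed Seed for feature placement.
#' @param mines_from Index of the first target to be reached with mines on
#'   top of the final road network (default: the last one).
#' @return Named list of calibrated [feature_set()]s with an
#'   `achieved_pct` attribute.
#' @export
calibrate_scenarios <- function(landscape, targets, buffer_width = 500,
                                resolution = 250, tol = 0.5, seed = 42,
                                mines_from = length(targets)) {
  stopifnot(inherits(landscape, "caribou_landscape"), length(targets) >= 1L)
  if (is.unsorted(targets)) stop("targets must be non-decreasing", call. = FALSE)
  pool <- .scenario_pool(landscape, seed)
  grid <- grid_for_range(landscape$range, resolution = resolution)
  measure <- function(road_m, mine_budget) {
    fs <- .assemble_scenario(pool, road_m, 1, mine_budget)
    if (nrow(fs) == 0L) return(0)
    area_fraction(rasterize_features(buffer_features(fs, buffer_width), grid),
                  landscape$range)
  }
  bisect <- function(f, lo, hi, target, iter = 40L) {
    flo <- f(lo)
    fhi <- f(hi)
    if (target < flo - tol || target > fhi + tol) {
      stop(sprintf("target %.2f%% not reachable in [%.2f, %.2f]",
                   target, flo, fhi), call. = FALSE)
    }
    for (i in seq_len(iter)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm - target) <= tol * 0.5) return(mid)
      if (fm < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  max_road <- sum(pool$road_lengths)
  achieved <- numeric(length(targets))
  out <- vector("list", length(targets))
  road_m <- 0
  for (i in seq_along(targets)) {
    if (i < mines_from) {
      road_m <- if (targets[i] <= 0) 0 else {
        bisect(function(L) measure(L, 0), road_m, max_road, targets[i])
      }
      out[[i]] <- .assemble_scenario(pool, road_m, 0, 0)
      achieved[i] <- measure(road_m, 0)
    } else {
      budget <- bisect(function(b) measure(road_m, b), 0, length(pool$mines),
                       targets[i])
      out[[i]] <- .assemble_scenario(pool, road_m, 1, budget)
      achieved[i] <- measure(road_m, budget)
    }
  }
  out <- stats::setNames(out, names(targets))
  attr(out, "achieved_pct") <- stats::setNames(achieved, names(targets))
  out
}

#' Simulate demographic observations with known truth
#'
#' Draws per-population, per-year survival and recruitment observations from
#' the package's own generative model (beta distributions around the
#' disturbance-predicted means, under the mean/precision parameterization),
#' at known covariates. Used for parameter-recovery and calibration checks
#' of the demographic machinery.
#'
#' @param model A [demographic_model()].
#' @param n_pops Number of populations.
#' @param years Observation years per population.
#' @param seed Integer seed.
#' @param covariates A [disturbance_covariates()] shared by all populations.
#' @return A tibble `(population_id, year, survival, recruitment)` (rates on
#'   the (0,1) scale, recruitment in calves per cow) with a `truth`
#'   attribute recording the generating means.
#' @export
generate_demographic_truth <- function(model, n_pops, years, seed = 42,
                                       covariates = disturbance_covariates(0, 0)) {
  stopifnot(inherits(model, "demographic_model"), n_pops >= 1L, years >= 1L)
  rates <- expected_rates(model, covariates)
  local_seed(seed, {
    n <- n_pops * years
    s <- stats::rbeta(n, rates$S_bar * model$precision_survival,
                      (1 - rates$S_bar) * model$precision_survival)
    r <- stats::rbeta(n, rates$R_bar * model$precision_recruitment,
                      (1 - rates$R_bar) * model$precision_recruitment)
    out <- tibble::tibble(
      population_id = rep(sprintf("pop%03d", seq_len(n_pops)), each = years),
      year = rep(seq_len(years), times = n_pops),
      survival = s,
      recruitment = r
    )
    attr(out, "truth") <- list(S_bar = rates$S_bar, R_bar = rates$R_bar,
                               lambda_bar = rates$lambda_bar,
                               covariates = covariates)
    out
  })
}
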