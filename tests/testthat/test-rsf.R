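toy_stack <- function(values_list, resolution = 100) {
  # build a predictor stack from plain matrices
  stack <- lapply(values_list, function(v) {
    raster_grid(as.matrix(v), resolution, origin = c(0, nrow(as.matrix(v)) * resolution))
  })
  structure(stack, class = "predictor_stack")
}

toy_table <- function(terms, transform = "exponential",
                      range_name = "Missisa", season = "spring") {
  rsf_table(
    tibble::tibble(range = range_name, season = season,
                   predictor = names(terms), coefficient = unname(terms),
                   transform = transform),
    range_name, season
  )
}

test_that("moving-window predictors behave on degenerate landscapes", {
  land <- generate_landscape(landscape_spec(
    extent_km = c(5, 5), resolution_m = 250,
    landcover_classes = c(conifer = 1), seed = 3
  ))
  stack <- derive_predictors(land, feature_set(), window_radius_m = 1000)
  expect_true(all(abs(stack$prop_conifer$values - 1) < 1e-9))
  expect_true(all(stack$road_density$values == 0))
  expect_error(
    derive_predictors(land, feature_set(), predictors = "elevation"),
    "unknown predictor"
  )
})

test_that("road density matches a brute-force length-in-window oracle", {
  land <- generate_landscape(landscape_spec(
    extent_km = c(3, 3), resolution_m = 100,
    landcover_classes = c(conifer = 1), seed = 8
  ))
  road_coords <- rbind(c(-100, 400), c(3100, 2500)) # one straight road
  scen <- feature_set(list(geom_line(road_coords)), "road")
  radius <- 500
  stack <- derive_predictors(land, scen, window_radius_m = radius)

  lc <- land$landcover
  lens <- oracle_cell_lengths(road_coords, lc)
  nr <- nrow(lens)
  nc <- ncol(lens)
  area_km2 <- window_cell_count(radius, 100) * 100^2 / 1e6
  # brute-force window sum at a handful of focal cells
  for (cell in list(c(5, 5), c(15, 15), c(22, 9), c(30, 30), c(1, 18))) {
    i <- cell[1]; j <- cell[2]
    tot <- 0
    for (di in -5:5) for (dj in -5:5) {
      if ((di * 100)^2 + (dj * 100)^2 <= radius^2) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          tot <- tot + lens[ii, jj]
        }
      }
    }
    expect_equal(stack$road_density$values[i, j], (tot / 1000) / area_km2,
                 tolerance = 1e-6)
  }
})

test_that("apply_rsf reproduces a hand-computed exponential surface", {
  stack <- toy_stack(list(
    habitat = matrix(c(0.2, 0.5, 0.9), 1, 3),
    roads = matrix(c(1.0, 0.0, 2.0), 1, 3)
  ))
  tbl <- toy_table(c(habitat = 1.5, roads = -0.7))
  surf <- apply_rsf(tbl, stack)
  eta <- 1.5 * c(0.2, 0.5, 0.9) - 0.7 * c(1.0, 0.0, 2.0)
  expect_equal(as.vector(surf$values$values), exp(eta) / max(exp(eta)),
               tolerance = 1e-12)
  expect_equal(max(surf$values$values), 1)

  # logistic transform, same stack
  lsurf <- apply_rsf(toy_table(c(habitat = 1.5, roads = -0.7),
                               transform = "logistic"), stack)
  w <- plogis(eta)
  expect_equal(as.vector(lsurf$values$values), w / max(w), tolerance = 1e-12)
})

test_that("exponential surfaces are invariant to constant shifts in eta", {
  set.seed(99)
  x <- matrix(runif(100), 10, 10)
  stack <- toy_stack(list(x = x, one = matrix(1, 10, 10)))
  s0 <- apply_rsf(toy_table(c(x = 2)), stack)
  s1 <- apply_rsf(toy_table(c(x = 2, one = 37.5)), stack)
  expect_equal(s0$values$values, s1$values$values, tolerance = 1e-12)
})

test_that("a single positive term preserves the predictor's cell ranking", {
  set.seed(21)
  x <- matrix(runif(64), 8, 8)
  surf <- apply_rsf(toy_table(c(x = 3.1)), toy_stack(list(x = x)))
  expect_identical(order(surf$values$values), order(x))
  # all-zero coefficients flatten the surface to 1 after rescaling
  flat <- apply_rsf(toy_table(c(x = 0)), toy_stack(list(x = x)))
  expect_true(all(flat$values$values == 1))
})

test_that("more roads never increase use under a negative road coefficient", {
  land <- test_landscape()
  scen <- calibrate_scenarios(land, c(base = 0.4, roads_only = 1.1),
                              seed = 5, mines_from = 3)
  coefs <- read_rsf_coefficients(
    system.file("extdata", "rsf_coefficients_illustrative.csv",
                package = "caribouscen")
  )
  tbl <- rsf_table(coefs, "Missisa", "spring")
  expect_lt(tbl$terms[["road_density"]], 0)
  stack_base <- derive_predictors(land, scen$base)
  stack_road <- derive_predictors(land, scen$roads_only)
  # nested scenarios only add roads (up to convolution round-off)
  expect_true(all(stack_road$road_density$values >=
                    stack_base$road_density$values - 1e-6))
  # habitat layers identical, so the linear predictor can only drop where
  # road density rose: compare eta cell-wise before any rescaling
  eta <- function(stack) {
    Reduce(`+`, purrr::imap(tbl$terms, function(beta, nm) beta * stack[[nm]]$values))
  }
  d_eta <- eta(stack_road) - eta(stack_base)
  expect_true(all(d_eta <= 1e-6))
  denser <- stack_road$road_density$values >
    stack_base$road_density$values + 1e-6
  expect_true(any(denser))
  expect_true(all(d_eta[denser] < 0))
})

test_that("missing predictors are reported by name", {
  stack <- toy_stack(list(x = matrix(1, 2, 2)))
  expect_error(apply_rsf(toy_table(c(x = 1, bog = 2, esker = 3)), stack),
               "bog, esker")
})

test_that("transferability report matches an independently coded correlation", {
  set.seed(31)
  mk_surface <- function(values, name) {
    structure(
      list(values = raster_grid(values, 100, origin = c(0, 1000)),
           season = "winter", source_range = name),
      class = "rsf_surface"
    )
  }
  a <- matrix(runif(400), 20, 20)
  a <- a / max(a)
  ref <- mk_surface(a, "Missisa")

  expect_equal(compare_surfaces(ref, ref)$pearson_r, 1.0)
  neg <- mk_surface(1 - a, "JamesBay")
  expect_equal(compare_surfaces(ref, neg)$pearson_r, -1.0)

  b <- matrix(runif(400), 20, 20)
  rep <- compare_surfaces(ref, mk_surface(b, "Nipigon"))
  x <- as.vector(a)
  y <- as.vector(b)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rep$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(nrow(rep$pairs), 400L)

  flat <- mk_surface(matrix(1, 20, 20), "Pagwachuan")
  expect_warning(dg <- compare_surfaces(ref, flat), "zero-variance")
  expect_true(dg$degenerate)
  expect_true(is.na(dg$pearson_r))

  tiny_a <- mk_surface(matrix(c(1, NA, NA, NA), 2, 2), "a")
  tiny_b <- mk_surface(matrix(c(1, 1, NA, NA), 2, 2), "b")
  expect_error(compare_surfaces(tiny_a, tiny_b), "fewer than 3")
})

test_that("seasonal tables are independent of one another", {
  coefs <- read_rsf_coefficients(
    system.file("extdata", "rsf_coefficients_illustrative.csv",
                package = "caribouscen")
  )
  spring <- rsf_table(coefs, "Missisa", "spring")
  winter <- rsf_table(coefs, "Missisa", "winter")
  expect_false(identical(spring$terms, winter$terms))
  expect_error(rsf_table(coefs, "Missisa", "moose season"))
  expect_error(rsf_table(coefs, "Atlantis", "spring"), "no coefficients")
})
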