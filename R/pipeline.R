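#' Validate a run configuration
#'
#' Checks a configuration list (usually from YAML) against the expected
#' schema before any computation: known blocks, required fields, value
#' ranges, and existence of referenced files. Unknown top-level keys are an
#' error so typos fail fast.
#'
#' @param config A named list, or a path to a YAML file.
#' @return The normalized config list (defaults filled in), invisibly
#'   classed `run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "output_dir", "landscape", "scenarios", "disturbance",
             "rsf", "demography", "simulation")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0L) {
    stop("unknown config block(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  config$seed <- as.integer(config$seed %||% 42)
  config$output_dir <- config$output_dir %||% "caribouscen-run"

  ls <- config$landscape %||% list()
  config$landscape <- landscape_spec(
    extent_km = unlist(ls$extent_km %||% c(40, 40)),
    resolution_m = ls$resolution_m %||% 250,
    fire_fraction = ls$fire_fraction %||% 0.05,
    fire_age_range = unlist(ls$fire_age_range %||% c(1, 60)),
    reference_year = ls$reference_year %||% 2020,
    seed = derive_seed(config$seed, "landscape")
  )

  sc <- config$scenarios %||% list()
  targets <- unlist(sc$targets %||%
                      c(base = 0.41, roads_only = 1.11, roads_and_mines = 16.91))
  if (is.null(names(targets)) || any(names(targets) == "")) {
    stop("scenarios$targets must be a named mapping of percentages", call. = FALSE)
  }
  if (any(targets < 0 | targets > 100)) {
    stop("scenario targets are percentages in [0, 100]", call. = FALSE)
  }
  config$scenarios <- list(targets = targets)

  db <- config$disturbance %||% list()
  config$disturbance <- list(
    buffer_width_m = db$buffer_width_m %||% 500,
    fire_horizon_y = db$fire_horizon_y %||% 40,
    resolution_m = db$resolution_m %||% config$landscape$resolution_m
  )
  if (config$disturbance$buffer_width_m < 0) {
    stop("buffer_width_m must be >= 0", call. = FALSE)
  }

  rsf <- config$rsf %||% list()
  coef_path <- rsf$coefficients %||%
    system.file("extdata", "rsf_coefficients_illustrative.csv", package = "caribouscen")
  if (!file.exists(coef_path)) {
    stop("RSF coefficient file not found: ", coef_path, call. = FALSE)
  }
  config$rsf <- list(
    coefficients = coef_path,
    window_radius_m = rsf$window_radius_m %||% 5000,
    seasons = unlist(rsf$seasons %||% c("spring", "summer", "fall", "winter")),
    reference_range = rsf$reference_range %||% "Missisa",
    transfer_ranges = unlist(rsf$transfer_ranges %||%
                               c("JamesBay", "Nipigon", "Pagwachuan")),
    scenario = rsf$scenario %||% names(targets)[min(2L, length(targets))]
  )
  if (!config$rsf$scenario %in% names(targets)) {
    stop("rsf$scenario must name one of the disturbance scenarios", call. = FALSE)
  }

  dm <- config$demography %||% list()
  model_path <- dm$model %||%
    system.file("extdata", "demographic_model_illustrative.yaml", package = "caribouscen")
  if (!file.exists(model_path)) {
    stop("demographic model file not found: ", model_path, call. = FALSE)
  }
  config$demography <- list(model = model_path)

  sim <- config$simulation %||% list()
  config$simulation <- list(
    years = sim$years %||% 20,
    n_pops = sim$n_pops %||% 500,
    initial_females = sim$initial_females %||% 100,
    carrying_capacity_multiplier = sim$carrying_capacity_multiplier %||% 5,
    interannual_precision_S = sim$interannual_precision_S %||% 400,
    interannual_precision_R = sim$interannual_precision_R %||% 60,
    self_sustaining_threshold = sim$self_sustaining_threshold %||% 0.99
  )
  structure(config, class = c("run_config", "list"))
}

#' Run the full scenario analysis
#'
#' End-to-end pipeline on a synthetic landscape: generate the landscape,
#' calibrate nested disturbance scenarios to the configured target
#' percentages, tabulate the disturbance summaries, project seasonal RSF
#' surfaces (reference range plus transfers) under the configured scenario,
#' score transferability, and project the demographic ensemble across
#' scenarios. Every stage is seeded from the single config seed, so a rerun
#' with the same config reproduces every output bit-for-bit.
#'
#' @param config A config list or YAML path (see [validate_run_config()]).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with all stage results plus the manifest; side
#'   effect: CSV/JSON/ASCII-grid outputs and `manifest.json` under
#'   `output_dir`.
#' @export
run_scenario_analysis <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("landscape: generating (seed %d)", config$landscape$seed)
  landscape <- generate_landscape(config$landscape)

  say("scenarios: calibrating to targets [%s]",
      paste(sprintf("%s=%.2f", names(config$scenarios$targets),
                    config$scenarios$targets), collapse = ", "))
  scen <- calibrate_scenarios(
    landscape, config$scenarios$targets,
    buffer_width = config$disturbance$buffer_width_m,
    resolution = config$disturbance$resolution_m,
    seed = derive_seed(config$seed, "scenarios")
  )

  say("disturbance: summarizing %d scenarios", length(scen))
  dist_tbl <- scenario_table(
    scen, landscape$fire, landscape$range,
    buffer_width = config$disturbance$buffer_width_m,
    fire_horizon = config$disturbance$fire_horizon_y,
    reference_year = config$landscape$reference_year,
    resolution = config$disturbance$resolution_m
  )
  write_disturbance_csv(dist_tbl, file.path(out_dir, "disturbance.csv"))

  say("rsf: projecting seasons [%s]", paste(config$rsf$seasons, collapse = ", "))
  coefs <- read_rsf_coefficients(config$rsf$coefficients)
  stack <- derive_predictors(landscape, scen[[config$rsf$scenario]],
                             window_radius_m = config$rsf$window_radius_m)
  transfer <- list()
  for (season in config$rsf$seasons) {
    ref <- apply_rsf(rsf_table(coefs, config$rsf$reference_range, season), stack)
    write_ascii_grid(ref$values,
                     file.path(out_dir, sprintf("rsf_%s_%s.asc",
                                                config$rsf$reference_range,
                                                season)))
    for (rng in config$rsf$transfer_ranges) {
      surf <- apply_rsf(rsf_table(coefs, rng, season), stack)
      rep <- compare_surfaces(ref, surf, thin_n = 2000,
                              seed = derive_seed(config$seed, "thin"))
      transfer[[paste(season, rng, sep = "_")]] <- glance(rep)
    }
  }
  transfer_tbl <- dplyr::bind_rows(transfer)
  utils::write.csv(transfer_tbl, file.path(out_dir, "transferability.csv"),
                   row.names = FALSE)

  say("demography: ensemble of %d populations x %d scenarios",
      config$simulation$n_pops, nrow(dist_tbl))
  model <- read_demographic_model(config$demography$model)
  covs <- purrr::map(seq_len(nrow(dist_tbl)), function(i) {
    disturbance_covariates(dist_tbl$pct_anthro[i],
                           dist_tbl$pct_fire_excl_anthro[i])
  })
  names(covs) <- dist_tbl$scenario
  opts <- simulation_options(
    years = config$simulation$years,
    initial_females = config$simulation$initial_females,
    interannual_precision_S = config$simulation$interannual_precision_S,
    interannual_precision_R = config$simulation$interannual_precision_R,
    carrying_capacity_multiplier = config$simulation$carrying_capacity_multiplier,
    self_sustaining_threshold = config$simulation$self_sustaining_threshold,
    seed = derive_seed(config$seed, "simulation")
  )
  ensemble <- run_ensemble(model, covs, opts, n_pops = config$simulation$n_pops)
  utils::write.csv(ensemble$summary, file.path(out_dir, "ensemble_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(ensemble$draws, file.path(out_dir, "ensemble_draws.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("caribouscen")),
    seed = config$seed,
    parameters = unclass(config[c("landscape", "scenarios", "disturbance",
                                  "rsf", "demography", "simulation")]),
    outputs = {
      files <- sort(setdiff(list.files(out_dir), "manifest.json"))
      as.list(tools::md5sum(file.path(out_dir, files)))
    }
  )
  manifest$parameters$landscape <- unclass(manifest$parameters$landscape)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: outputs in %s", out_dir)
  invisible(list(landscape = landscape, scenarios = scen,
                 disturbance = dist_tbl, transferability = transfer_tbl,
                 ensemble = ensemble, manifest = manifest,
                 config = config))
}
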