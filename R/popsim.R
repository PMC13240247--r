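#' Options for stochastic population projection
#'
#' Controls the three stochastic layers of the projection: interannual
#' variation (annual beta draws around the population's mean rates),
#' demographic stochasticity (binomial survival and recruitment in a
#' female-only model), and density dependence (a hard ceiling
#' `K = carrying_capacity_multiplier * initial_females`).
#'
#' @param years Projection horizon (default 20).
#' @param initial_females Starting adult-female count `N0` (default 100).
#' @param interannual_precision_S,interannual_precision_R Beta precisions of
#'   the annual draws around the population means (larger = less
#'   year-to-year variation).
#' @param interannual_variation Draw annual rates (default TRUE); when
#'   FALSE the population means are used every year.
#' @param demographic_stochasticity Binomial demographic sampling (default
#'   TRUE); when FALSE expectations are propagated (continuous counts).
#' @param carrying_capacity_multiplier Ceiling multiplier `c >= 1`,
#'   `K = c * N0` (default 5).
#' @param self_sustaining_threshold Realized growth below this marks a
#'   population not self-sustaining (default 0.99).
#' @param seed Integer seed; population `i` of an ensemble runs on stream
#'   `seed + i`, so results are reproducible and order-independent.
#' @return An object of class `simulation_options`.
#' @export
simulation_options <- function(years = 20, initial_females = 100,
                               interannual_precision_S = 400,
                               interannual_precision_R = 60,
                               interannual_variation = TRUE,
                               demographic_stochasticity = TRUE,
                               carrying_capacity_multiplier = 5,
                               self_sustaining_threshold = 0.99,
                               seed = 42) {
  stopifnot(years >= 1, initial_females >= 1,
            carrying_capacity_multiplier >= 1,
            interannual_precision_S > 0, interannual_precision_R > 0,
            self_sustaining_threshold > 0, self_sustaining_threshold < 2)
  structure(
    list(years = as.integer(years),
         initial_females = as.integer(initial_females),
         interannual_precision_S = interannual_precision_S,
         interannual_precision_R = interannual_precision_R,
         interannual_variation = isTRUE(interannual_variation),
         demographic_stochasticity = isTRUE(demographic_stochasticity),
         carrying_capacity_multiplier = carrying_capacity_multiplier,
         self_sustaining_threshold = self_sustaining_threshold,
         seed = as.integer(seed)),
    class = "simulation_options"
  )
}

#' Project one population
#'
#' Female-only yearly loop with a 50% calf sex ratio. Each year the annual
#' survival `S_t` and recruitment `R_t` (calves per cow) are drawn from beta
#' distributions around the population means (or equal to them when
#' interannual variation is off); survivors are `Binomial(N_t, S_t)`;
#' recruited females are `Binomial(survivors, min(R_t / 2, 1))` (recruitment
#' applies to survivors, and the per-capita female-calf probability is
#' clamped to keep the binomial well defined); the ceiling `K` is then
#' applied. Extinction (`N = 0`) is absorbing. With demographic
#' stochasticity off, expectations replace the binomial draws and the
#' deterministic skeleton reproduces `lambda_bar = S (1 + R/2)` exactly
#' below the ceiling.
#'
#' @param S_pop Population mean annual survival in (0, 1).
#' @param R_pop Population mean recruitment, calves per cow (>= 0; must be
#'   in (0, 1) when interannual variation is on).
#' @param options A [simulation_options()].
#' @return A tibble of class `caribou_trajectory` with columns `year`
#'   (0..years), `N`, `S_t`, `R_t` (rates acting between `year - 1` and
#'   `year`; `NA` at year 0), and attributes `realized_lambda` and
#'   `extinct`.
#' @export
simulate_population <- function(S_pop, R_pop, options = simulation_options()) {
  if (!is.numeric(S_pop) || S_pop <= 0 || S_pop >= 1) {
    stop("`S_pop` must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(R_pop) || R_pop < 0) {
    stop("`R_pop` must be >= 0 (calves per cow)", call. = FALSE)
  }
  if (options$interannual_variation && R_pop >= 1) {
    stop("`R_pop` must be in (0, 1) when interannual variation is on",
         call. = FALSE)
  }
  tyears <- options$years
  K <- options$carrying_capacity_multiplier * options$initial_females
  N <- numeric(tyears + 1L)
  S_t <- R_t <- c(NA_real_, numeric(tyears))
  N[1] <- options$initial_females
  local_seed(options$seed, {
    for (t in seq_len(tyears)) {
      if (options$interannual_variation) {
        s <- stats::rbeta(1, S_pop * options$interannual_precision_S,
                          (1 - S_pop) * options$interannual_precision_S)
        r <- stats::rbeta(1, R_pop * options$interannual_precision_R,
                          (1 - R_pop) * options$interannual_precision_R)
      } else {
        s <- S_pop
        r <- R_pop
      }
      S_t[t + 1L] <- s
      R_t[t + 1L] <- r
      p_calf <- min(r / 2, 1)
      if (N[t] <= 0) {
        N[t + 1L] <- 0
      } else if (options$demographic_stochasticity) {
        surv <- stats::rbinom(1, round(N[t]), s)
        juv <- stats::rbinom(1, surv, p_calf)
        N[t + 1L] <- min(surv + juv, K)
      } else {
        N[t + 1L] <- min(N[t] * s * (1 + p_calf), K)
      }
    }
  })
  out <- tibble::tibble(year = 0:tyears, N = N, S_t = S_t, R_t = R_t)
  class(out) <- c("caribou_trajectory", class(out))
  attr(out, "realized_lambda") <- .lambda_from_counts(N)
  attr(out, "extinct") <- N[tyears + 1L] == 0
  attr(out, "options") <- options
  out
}

.lambda_from_counts <- function(N) {
  T <- length(N) - 1L
  if (N[1] <= 0) stop("initial population size must be positive", call. = FALSE)
  if (N[T + 1L] == 0) return(0)
  (N[T + 1L] / N[1])^(1 / T)
}

#' Realized growth rate of a trajectory
#'
#' Geometric-mean annual growth over the horizon, `(N_T / N_0)^(1/T)`;
#' zero (extinct) when the final count is zero.
#'
#' @param traj A [simulate_population()] trajectory, or any data frame with
#'   `N` ordered by year.
#' @return A single growth rate (>= 0).
#' @export
realized_lambda <- function(traj) {
  N <- traj$N
  if (length(N) < 2L) stop("trajectory must span at least one year", call. = FALSE)
  .lambda_from_counts(N)
}

#' Run a scenario ensemble
#'
#' Samples `n_pops` among-population quantiles **once** and holds them fixed
#' across scenarios (quantile persistence): a population keeps its rank in
#' the among-population distribution as disturbance changes, so scenario
#' contrasts are paired. Each population is then projected with
#' [simulate_population()] on its own RNG stream, and realized growth rates
#' are summarized per scenario.
#'
#' @param model A [demographic_model()].
#' @param scenarios Named list of [disturbance_covariates()], one per
#'   scenario.
#' @param options A [simulation_options()].
#' @param n_pops Number of sample populations (default 500).
#' @param stratified Stratified quantile sampling (default TRUE).
#' @return An object of class `caribou_ensemble`: list with `summary` (one
#'   row per scenario: lambda quantiles 2.5/25/50/75/97.5%, expected
#'   `lambda_bar`, `prop_not_self_sustaining`, `n_pops`), `draws` (one row
#'   per scenario x population), `quantiles`, and `options`.
#' @export
run_ensemble <- function(model, scenarios, options = simulation_options(),
                         n_pops = 500, stratified = TRUE) {
  stopifnot(inherits(model, "demographic_model"), length(scenarios) >= 1L)
  if (n_pops < 1) stop("`n_pops` must be >= 1", call. = FALSE)
  labels <- names(scenarios)
  if (is.null(labels) || any(labels == "")) {
    stop("`scenarios` must be a named list of covariates", call. = FALSE)
  }
  pq <- sample_population_quantiles(
    n_pops, seed = derive_seed(options$seed, "quantiles"),
    stratified = stratified
  )
  draws <- purrr::map_dfr(labels, function(lab) {
    rates <- rates_at_quantile(model, scenarios[[lab]], pq)
    lam <- purrr::map_dbl(seq_len(nrow(rates)), function(i) {
      opt_i <- options
      opt_i$seed <- options$seed + i
      traj <- simulate_population(rates$S[i], rates$R[i], opt_i)
      attr(traj, "realized_lambda")
    })
    dplyr::mutate(rates, scenario = lab, realized_lambda = lam,
                  .before = 1L)
  })
  thr <- options$self_sustaining_threshold
  summary <- draws |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      lambda_q025 = stats::quantile(.data$realized_lambda, 0.025),
      lambda_q25 = stats::quantile(.data$realized_lambda, 0.25),
      lambda_median = stats::median(.data$realized_lambda),
      lambda_q75 = stats::quantile(.data$realized_lambda, 0.75),
      lambda_q975 = stats::quantile(.data$realized_lambda, 0.975),
      prop_not_self_sustaining = mean(.data$realized_lambda < thr),
      n_pops = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(scenario = factor(.data$scenario, levels = labels)) |>
    dplyr::arrange(.data$scenario) |>
    dplyr::mutate(scenario = as.character(.data$scenario))
  exp_rates <- purrr::map_dfr(labels, function(lab) {
    er <- expected_rates(model, scenarios[[lab]])
    tibble::tibble(scenario = lab, lambda_bar = er$lambda_bar,
                   S_bar = er$S_bar, R_bar_per100 = er$R_bar_per100)
  })
  summary <- dplyr::left_join(summary, exp_rates, by = "scenario")
  structure(list(summary = summary, draws = draws, quantiles = pq,
                 options = options),
            class = "caribou_ensemble")
}

#' @export
print.caribou_ensemble <- function(x, ...) {
  cat(sprintf("<caribou_ensemble> %d populations x %d scenarios, %d years\n",
              x$summary$n_pops[1], nrow(x$summary), x$options$years))
  print(x$summary)
  invisible(x)
}

#' Tidy an ensemble
#'
#' @param x A [run_ensemble()] result.
#' @param ... Unused.
#' @return The per-population draws tibble (`scenario`, `population_id`,
#'   `q_S`, `q_R`, `S`, `R`, `lambda_bar`, `realized_lambda`).
#' @export
tidy.caribou_ensemble <- function(x, ...) x$draws

#' @rdname tidy.caribou_ensemble
#' @export
glance.caribou_ensemble <- function(x, ...) x$summary
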