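#' Disturbance covariates for the demographic model
#'
#' The two range-level covariates driving national survival/recruitment
#' regressions: percent of the range in the 500 m-buffered anthropogenic
#' footprint, and percent burned within the fire horizon but outside that
#' footprint.
#'
#' @param anthro Buffered anthropogenic disturbance, percent (0-100).
#' @param fire_excl_anthro Fire excluding anthropogenic, percent (0-100).
#' @return An object of class `disturbance_covariates`.
#' @export
disturbance_covariates <- function(anthro, fire_excl_anthro = 0) {
  if (anthro < 0 || anthro > 100 || fire_excl_anthro < 0 ||
      fire_excl_anthro > 100) {
    stop("covariates are percentages and must lie in [0, 100]", call. = FALSE)
  }
  structure(list(anthro = anthro, fire_excl_anthro = fire_excl_anthro),
            class = "disturbance_covariates")
}

#' Covariates from a disturbance summary
#' @param summary A [summarize_disturbance()] row.
#' @return A [disturbance_covariates()].
#' @export
covariates_from_summary <- function(summary) {
  disturbance_covariates(summary$pct_anthro[1], summary$pct_fire_excl_anthro[1])
}

.linkinv <- function(link) {
  switch(link,
    logit = stats::plogis,
    log = exp,
    identity = identity,
    stop("unknown link: ", link, call. = FALSE)
  )
}

#' Define a disturbance-demography model
#'
#' Beta regressions for expected adult female survival and recruitment as
#' functions of range disturbance, each with a precision parameter phi
#' under the mean/precision parameterization
#' (`alpha = mu * phi`, `beta = (1 - mu) * phi`).
#' Recruitment is handled in calves per 100 cows at the interface (the
#' reporting convention) and calves per cow internally.
#'
#' @param survival,recruitment Lists with elements `link` (`"logit"`,
#'   `"log"`, or `"identity"`), `intercept`, `coef_anthro`, optional
#'   `coef_fire`, and `precision` (> 0). The recruitment linear predictor is
#'   on the calves-per-100-cows scale.
#' @param model_id_survival,model_id_recruitment Labels for provenance
#'   (defaults `"M4"` and `"M1"`, the conventional top-ranked national
#'   model forms).
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(survival, recruitment,
                              model_id_survival = "M4",
                              model_id_recruitment = "M1") {
  need <- function(term, who) {
    if (is.null(term$link) || is.null(term$intercept) ||
        is.null(term$coef_anthro) || is.null(term$precision)) {
      stop(who, " needs `link`, `intercept`, `coef_anthro`, `precision`",
           call. = FALSE)
    }
    if (term$precision <= 0) stop(who, " precision must be > 0", call. = FALSE)
    term$coef_fire <- term$coef_fire %||% 0
    term
  }
  structure(
    list(survival = need(survival, "survival"),
         recruitment = need(recruitment, "recruitment"),
         model_id_survival = model_id_survival,
         model_id_recruitment = model_id_recruitment,
         precision_survival = survival$precision,
         precision_recruitment = recruitment$precision),
    class = "demographic_model"
  )
}

#' Read a demographic model from YAML
#'
#' Schema: top-level `survival` and `recruitment` blocks, each with `link`,
#' `intercept`, `coef_anthro`, optional `coef_fire`, and `precision`;
#' optional `model_id` per block. The package ships an illustrative default
#' at `system.file("extdata", "demographic_model_illustrative.yaml", package =
#' "caribouscen")` — synthetic coefficients producing declining rates with
#' disturbance, not the published national values.
#'
#' @param path YAML file path.
#' @return A [demographic_model()].
#' @export
read_demographic_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$survival) || is.null(y$recruitment)) {
    stop("model YAML needs `survival` and `recruitment` blocks", call. = FALSE)
  }
  demographic_model(
    survival = y$survival, recruitment = y$recruitment,
    model_id_survival = y$survival$model_id %||% "M4",
    model_id_recruitment = y$recruitment$model_id %||% "M1"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf(
    "<demographic_model> survival %s (%s link, phi=%g); recruitment %s (%s link, phi=%g)\n",
    x$model_id_survival, x$survival$link, x$precision_survival,
    x$model_id_recruitment, x$recruitment$link, x$precision_recruitment
  ))
  invisible(x)
}

#' Expected demographic rates at given disturbance
#'
#' Applies the inverse link to each linear predictor and combines the rates
#' into the expected annual growth of the adult-female segment,
#' `lambda_bar = S_bar * (1 + R_bar / 2)` — the female-only form under a
#' 50% calf sex ratio.
#'
#' @param model A [demographic_model()].
#' @param covariates A [disturbance_covariates()].
#' @return A one-row tibble of class `expected_rates`: `S_bar` (annual
#'   adult female survival), `R_bar` (calves per cow), `R_bar_per100`
#'   (calves per 100 cows, the reporting unit), `lambda_bar`.
#' @export
expected_rates <- function(model, covariates) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(covariates, "disturbance_covariates"))
  eta <- function(term) {
    term$intercept + term$coef_anthro * covariates$anthro +
      term$coef_fire * covariates$fire_excl_anthro
  }
  S <- .linkinv(model$survival$link)(eta(model$survival))
  if (S <= 0 || S >= 1) {
    warning(sprintf("survival prediction %.4f outside (0,1); clamped", S),
            call. = FALSE)
    S <- min(1 - 1e-6, max(1e-6, S))
  }
  R100 <- .linkinv(model$recruitment$link)(eta(model$recruitment))
  if (R100 < 0) stop("negative recruitment prediction", call. = FALSE)
  R <- R100 / 100
  out <- tibble::tibble(S_bar = S, R_bar = R, R_bar_per100 = R100,
                        lambda_bar = S * (1 + R / 2))
  class(out) <- c("expected_rates", class(out))
  out
}

#' Sample among-population quantiles
#'
#' Populations differ persistently: each is assigned quantiles `(q_S, q_R)`
#' of the among-population beta distributions, which it keeps as
#' disturbance changes (rank-preserving trajectories). Stratified sampling
#' draws one quantile uniformly within each of `n` equal-probability bins
#' per rate (bins independently permuted between rates so `q_S` and `q_R`
#' stay unrelated); otherwise quantiles are i.i.d. uniform.
#'
#' @param n Number of populations (default 500).
#' @param seed Integer seed.
#' @param stratified One quantile per equal-probability bin (default TRUE).
#' @param shared Force `q_R = q_S` (default FALSE: independent).
#' @return A tibble `(population_id, q_S, q_R)`, quantiles strictly in
#'   (0, 1).
#' @export
sample_population_quantiles <- function(n = 500, seed = 42,
                                        stratified = TRUE, shared = FALSE) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  n <- as.integer(n)
  local_seed(seed, {
    draw <- function() {
      if (stratified) {
        (seq_len(n) - stats::runif(n)) / n
      } else {
        stats::runif(n)
      }
    }
    q_s <- draw()
    q_r <- if (shared) q_s else if (stratified) sample(draw()) else draw()
    tibble::tibble(
      population_id = sprintf("pop%03d", seq_len(n)),
      q_S = pmin(1 - 1e-12, pmax(1e-12, q_s)),
      q_R = pmin(1 - 1e-12, pmax(1e-12, q_r))
    )
  })
}

#' Beta quantiles under the mean/precision parameterization
#'
#' `qbeta_mp(p, mu, phi)` is the inverse CDF of
#' `Beta(alpha = mu * phi, beta = (1 - mu) * phi)`; `pbeta_mp` is the CDF.
#'
#' @param p Probabilities.
#' @param q Quantile values in (0,1).
#' @param mu Mean in (0, 1).
#' @param phi Precision (> 0).
#' @export
qbeta_mp <- function(p, mu, phi) {
  if (any(mu <= 0 | mu >= 1)) stop("`mu` must be in (0, 1)", call. = FALSE)
  if (any(phi <= 0)) stop("`phi` must be > 0", call. = FALSE)
  stats::qbeta(p, mu * phi, (1 - mu) * phi)
}

#' @rdname qbeta_mp
#' @export
pbeta_mp <- function(q, mu, phi) {
  stats::pbeta(q, mu * phi, (1 - mu) * phi)
}

#' Population-specific rates at fixed quantiles
#'
#' Evaluates each population's survival and recruitment as the `q`-th
#' quantile of the among-population beta distribution centred on the
#' expected rates: `S = QBeta(q_S; mu = S_bar, phi_S)` and likewise for
#' recruitment on the calves-per-cow scale (which must lie in (0, 1) for
#' the beta distribution to apply).
#'
#' @param model A [demographic_model()].
#' @param covariates A [disturbance_covariates()].
#' @param quantiles Tibble from [sample_population_quantiles()], or any
#'   data frame with `q_S` and `q_R` in (0, 1).
#' @return `quantiles` with columns `S`, `R` (calves per cow), and
#'   `lambda_bar` (the per-population deterministic growth rate
#'   `S * (1 + R / 2)`) appended.
#' @export
rates_at_quantile <- function(model, covariates, quantiles) {
  stopifnot(inherits(model, "demographic_model"),
            all(c("q_S", "q_R") %in% names(quantiles)))
  if (any(quantiles$q_S <= 0 | quantiles$q_S >= 1 |
          quantiles$q_R <= 0 | quantiles$q_R >= 1)) {
    stop("quantiles must be strictly in (0, 1)", call. = FALSE)
  }
  er <- expected_rates(model, covariates)
  if (er$R_bar <= 0 || er$R_bar >= 1) {
    stop("mean recruitment must be in (0, 1) calves per cow for the beta layer",
         call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(quantiles),
    S = qbeta_mp(.data$q_S, er$S_bar, model$precision_survival),
    R = qbeta_mp(.data$q_R, er$R_bar, model$precision_recruitment),
    lambda_bar = .data$S * (1 + .data$R / 2)
  )
}

# --- broom-style methods -----------------------------------------------------

#' Tidy a demographic model
#'
#' @param x A [demographic_model()].
#' @param ... Unused.
#' @return One row per regression term: `response`, `model_id`, `link`,
#'   `term`, `estimate`.
#' @export
tidy.demographic_model <- function(x, ...) {
  row <- function(resp, id, tm) {
    tibble::tibble(
      response = resp, model_id = id, link = tm$link,
      term = c("intercept", "anthro", "fire_excl_anthro"),
      estimate = c(tm$intercept, tm$coef_anthro, tm$coef_fire)
    )
  }
  dplyr::bind_rows(
    row("survival", x$model_id_survival, x$survival),
    row("recruitment", x$model_id_recruitment, x$recruitment)
  )
}

#' @rdname tidy.demographic_model
#' @export
glance.demographic_model <- function(x, ...) {
  tibble::tibble(
    model_id_survival = x$model_id_survival,
    model_id_recruitment = x$model_id_recruitment,
    precision_survival = x$precision_survival,
    precision_recruitment = x$precision_recruitment
  )
}
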