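test_that("lambda_bar follows the Hatter-Bergerud identity exactly", {
  # identity-link model lets us pin the rates directly
  mk <- function(S, R100) demographic_model(
    survival = list(link = "identity", intercept = S, coef_anthro = 0,
                    precision = 10),
    recruitment = list(link = "identity", intercept = R100, coef_anthro = 0,
                       precision = 10)
  )
  cov0 <- disturbance_covariates(0, 0)
  r1 <- expected_rates(mk(0.8, 50), cov0) # R = 0.5 calves/cow
  expect_identical(r1$lambda_bar, 0.8 * (1 + 0.5 / 2))
  expect_identical(r1$lambda_bar, 1.0)

  r2 <- expected_rates(mk(0.999999, 0), cov0)
  expect_equal(r2$lambda_bar, r2$S_bar)

  set.seed(2)
  for (i in 1:20) {
    S <- runif(1, 0.5, 0.99)
    R100 <- runif(1, 5, 60)
    r <- expected_rates(mk(S, R100), cov0)
    expect_identical(r$lambda_bar, r$S_bar * (1 + r$R_bar / 2))
    expect_identical(r$R_bar, r$R_bar_per100 / 100)
  }
})

test_that("rates decline monotonically over a disturbance grid", {
  model <- toy_model()
  grid <- seq(0, 50, by = 5)
  rates <- purrr::map_dfr(grid, function(a) {
    expected_rates(model, disturbance_covariates(a, 0))
  })
  expect_true(all(diff(rates$S_bar) < 0))
  expect_true(all(diff(rates$R_bar) < 0))
  expect_true(all(diff(rates$lambda_bar) < 0))
  # direct inverse-link evaluation as the oracle
  expect_equal(rates$S_bar, plogis(2.2 - 0.02 * grid), tolerance = 1e-12)
  expect_equal(rates$R_bar_per100, exp(3.35 - 0.011 * grid), tolerance = 1e-12)
})

test_that("out-of-range predictions are clamped or rejected", {
  wild <- demographic_model(
    survival = list(link = "identity", intercept = 1.4, coef_anthro = 0,
                    precision = 10),
    recruitment = list(link = "log", intercept = 3, coef_anthro = 0,
                       precision = 10)
  )
  expect_warning(r <- expected_rates(wild, disturbance_covariates(0, 0)),
                 "clamped")
  expect_lt(r$S_bar, 1)

  neg <- demographic_model(
    survival = list(link = "logit", intercept = 2, coef_anthro = 0,
                    precision = 10),
    recruitment = list(link = "identity", intercept = -5, coef_anthro = 0,
                       precision = 10)
  )
  expect_error(expected_rates(neg, disturbance_covariates(0, 0)),
               "negative recruitment")
  expect_error(disturbance_covariates(120, 0), "0, 100")
  expect_error(
    demographic_model(
      survival = list(link = "logit", intercept = 2, coef_anthro = 0,
                      precision = -1),
      recruitment = list(link = "log", intercept = 3, coef_anthro = 0,
                         precision = 10)
    ),
    "precision"
  )
})

test_that("stratified quantiles occupy every bin; i.i.d. quantiles are uniform", {
  one <- sample_population_quantiles(1, seed = 5)
  expect_equal(nrow(one), 1L)
  expect_true(one$q_S > 0 && one$q_S < 1)

  ten <- sample_population_quantiles(10, seed = 6, stratified = TRUE)
  expect_identical(findInterval(sort(ten$q_S), seq(0, 1, 0.1),
                                rightmost.closed = TRUE), 1:10)
  expect_identical(findInterval(sort(ten$q_R), seq(0, 1, 0.1),
                                rightmost.closed = TRUE), 1:10)
  # independent permutation: q_R is not just q_S reordered bin-by-bin
  expect_false(identical(order(ten$q_S), order(ten$q_R)))

  shared <- sample_population_quantiles(10, seed = 6, shared = TRUE)
  expect_identical(shared$q_S, shared$q_R)

  iid <- sample_population_quantiles(10000, seed = 7, stratified = FALSE)
  ks <- suppressWarnings(stats::ks.test(iid$q_S, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(sample_population_quantiles(0), ">= 1")
  # determinism
  expect_identical(sample_population_quantiles(50, seed = 3),
                   sample_population_quantiles(50, seed = 3))
})

test_that("beta inverse CDF agrees with numeric root finding to 1e-8", {
  set.seed(17)
  for (i in 1:20) {
    mu <- runif(1, 0.05, 0.95)
    phi <- runif(1, 2, 300)
    q <- runif(1, 0.01, 0.99)
    got <- qbeta_mp(q, mu, phi)
    # independent oracle: root of the regularized incomplete beta CDF
    root <- uniroot(
      function(x) stats::pbeta(x, mu * phi, (1 - mu) * phi) - q,
      interval = c(1e-12, 1 - 1e-12), tol = 1e-12
    )$root
    expect_equal(got, root, tolerance = 1e-8)
  }
  expect_error(qbeta_mp(0.5, 1.2, 10), "mu")
  expect_error(qbeta_mp(0.5, 0.5, -1), "phi")
})

test_that("population rates collapse to the mean at extreme precision", {
  model <- toy_model(phi_S = 1e6, phi_R = 1e6)
  cov <- disturbance_covariates(10, 5)
  er <- expected_rates(model, cov)
  pq <- tibble::tibble(population_id = c("a", "b"), q_S = c(0.2, 0.8),
                       q_R = c(0.3, 0.7))
  rr <- rates_at_quantile(model, cov, pq)
  expect_true(all(abs(rr$S - er$S_bar) < 1e-3))
  expect_true(all(abs(rr$R - er$R_bar) < 1e-3))
})

test_that("rates are strictly monotone in the quantile", {
  model <- toy_model()
  cov <- disturbance_covariates(5, 0)
  pq <- tibble::tibble(population_id = c("lo", "hi"), q_S = c(0.25, 0.75),
                       q_R = c(0.25, 0.75))
  rr <- rates_at_quantile(model, cov, pq)
  expect_lt(rr$S[1], rr$S[2])
  expect_lt(rr$R[1], rr$R[2])
  expect_error(rates_at_quantile(model, cov,
                                 tibble::tibble(q_S = 0, q_R = 0.5)),
               "strictly in")
})

test_that("quantile-persistent trajectories never cross over disturbance", {
  model <- toy_model()
  pq <- sample_population_quantiles(25, seed = 9)
  grid <- seq(0, 60, by = 3)
  S_mat <- sapply(grid, function(a) {
    rates_at_quantile(model, disturbance_covariates(a, 0), pq)$S
  })
  R_mat <- sapply(grid, function(a) {
    rates_at_quantile(model, disturbance_covariates(a, 0), pq)$R
  })
  rank_S <- apply(S_mat, 2, rank)
  rank_R <- apply(R_mat, 2, rank)
  expect_true(all(rank_S == rank_S[, 1])) # comonotone: ranks preserved
  expect_true(all(rank_R == rank_R[, 1]))
})

test_that("mean over i.i.d. quantiles recovers the expected rate", {
  model <- toy_model()
  cov <- disturbance_covariates(2, 1)
  er <- expected_rates(model, cov)
  pq <- sample_population_quantiles(10000, seed = 13, stratified = FALSE)
  rr <- rates_at_quantile(model, cov, pq)
  se_S <- sqrt(er$S_bar * (1 - er$S_bar) / (1 + model$precision_survival) /
                 nrow(rr))
  expect_lt(abs(mean(rr$S) - er$S_bar), 3 * se_S)
  se_R <- sqrt(er$R_bar * (1 - er$R_bar) / (1 + model$precision_recruitment) /
                 nrow(rr))
  expect_lt(abs(mean(rr$R) - er$R_bar), 3 * se_R)
})

test_that("the 2.5-97.5% band of sampled rates matches the beta interval", {
  model <- toy_model()
  cov <- disturbance_covariates(1, 0)
  er <- expected_rates(model, cov)
  # stratified quantiles at large n reproduce the predictive interval
  pq <- sample_population_quantiles(200000, seed = 4, stratified = TRUE)
  rr <- rates_at_quantile(model, cov, pq)
  band <- quantile(rr$S, c(0.025, 0.975), type = 1)
  want <- qbeta_mp(c(0.025, 0.975), er$S_bar, model$precision_survival)
  expect_equal(unname(band), want, tolerance = 1e-4)
  # and the quantile function itself is the analytic band, exactly
  expect_equal(qbeta_mp(c(0.025, 0.975), er$S_bar, model$precision_survival),
               qbeta(c(0.025, 0.975), er$S_bar * model$precision_survival,
                     (1 - er$S_bar) * model$precision_survival),
               tolerance = 1e-6)
})

test_that("model YAML round-trips through the documented schema", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "survival:",
    "  model_id: M4",
    "  link: logit",
    "  intercept: 2.0",
    "  coef_anthro: -0.03",
    "  precision: 45",
    "recruitment:",
    "  model_id: M1",
    "  link: log",
    "  intercept: 3.2",
    "  coef_anthro: -0.015",
    "  coef_fire: -0.002",
    "  precision: 12"
  ), path)
  m <- read_demographic_model(path)
  expect_s3_class(m, "demographic_model")
  expect_equal(m$survival$coef_fire, 0) # optional term defaults to zero
  expect_equal(m$recruitment$coef_fire, -0.002)
  td <- tidy(m)
  expect_equal(nrow(td), 6L)
  expect_equal(td$estimate[td$response == "survival" & td$term == "anthro"],
               -0.03)
  gl <- glance(m)
  expect_equal(gl$precision_recruitment, 12)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("survival: {link: logit}", bad)
  expect_error(read_demographic_model(bad), "blocks")
})
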