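test_that("candidate partition is the set difference with a guard", {
  expect_identical(partition_candidates(c(3L, 7L), c(7L, 12L)), 3L)
  expect_error(partition_candidates(c(3L, 7L), c(3L, 7L, 9L)),
               "no valid instruments")
})

test_that("stage-1 recovers the instrument coefficients", {
  d <- generate_dataset(scenario_config("s1", n = 5000, seed = 31))
  Z <- d$covariates[, d$truth$iv_cols]  # generation order (Z1, Z2)
  s1 <- fit_exposure_model(Z, d$exposure)
  # omitted-confounder attenuation is expected and tolerated
  expect_lt(max(abs(s1$eta_hat - c(1.0, 1.5))), 0.15)
  expect_true(all(s1$se_eta > 0))
  expect_length(s1$instrument_index, 5000L)
})

test_that("stage-1 degenerate inputs are caught", {
  d <- generate_dataset(small_config(n = 200, seed = 32))
  Z <- cbind(d$covariates[, d$truth$iv_cols[1]], 1)
  expect_warning(s1 <- fit_exposure_model(Z, d$exposure), "zero-variance")
  expect_length(s1$eta_hat, 1L)
  # a binary instrument equal to the exposure separates completely
  expect_error(
    suppressWarnings(fit_exposure_model(cbind(d$exposure), d$exposure)),
    "separation")
})

test_that("stage-2 Cox model estimates mediator effects and reports HRs", {
  d <- generate_dataset(small_config(n = 400, seed = 33))
  M <- d$covariates[, d$truth$all_structured]
  s1 <- fit_exposure_model(d$covariates[, d$truth$iv_cols], d$exposure)
  s2 <- fit_outcome_model_iv(s1$instrument_index, M, d$time, d$event)
  expect_length(s2$gamma_hat, 4L)
  expect_true(all(s2$se_gamma > 0))
  # hazard-ratio link consistency
  expect_equal(s2$hr$hr > 1, s2$hr$estimate > 0)
  # zero-variance mediator columns are dropped with a warning and report 0
  M2 <- cbind(M, dead = 0)
  expect_warning(s2b <- fit_outcome_model_iv(s1$instrument_index, M2,
                                             d$time, d$event),
                 "zero-variance")
  expect_identical(unname(s2b$gamma_hat["dead"]), 0)
})

test_that("mediator OLS models are exact on noiseless two-level data", {
  x <- c(0, 1, 0, 1)
  M <- cbind(m = c(0.1, 0.9, 0.1, 0.9))
  f <- fit_mediator_models(x, M)
  expect_equal(unname(f$lambda_hat), 0.8)
  expect_equal(unname(f$c_hat), 0.1)
})

test_that("mediator OLS slopes have the expected sampling behavior", {
  d <- generate_dataset(scenario_config("s1", n = 800, seed = 34))
  M <- d$covariates[, d$truth$all_structured]
  f <- fit_mediator_models(d$exposure, M)
  expect_lt(max(abs(unname(f$lambda_hat)[1:2] - c(0.8, 1.2))), 0.1)
  expect_lt(max(abs(unname(f$lambda_hat) - c(0.8, 1.2, 0, 1.5))), 0.2)
  # independent mediator: null slope at large n
  set.seed(35)
  xn <- rbinom(10000, 1, 0.5)
  fn <- fit_mediator_models(xn, cbind(rnorm(10000)))
  expect_lt(abs(unname(fn$lambda_hat)), 0.05)
})

test_that("the indirect product is invariant to mediator rescaling", {
  d <- generate_dataset(small_config(n = 400, seed = 36))
  M <- d$covariates[, d$truth$all_structured]
  s1 <- fit_exposure_model(d$covariates[, d$truth$iv_cols], d$exposure)
  est <- function(M) {
    s2 <- fit_outcome_model_iv(s1$instrument_index, M, d$time, d$event)
    lam <- fit_mediator_models(d$exposure, M)$lambda_hat
    unname(lam * s2$gamma_hat)
  }
  e1 <- est(M)
  Ms <- M
  Ms[, 1] <- 5 * Ms[, 1] + 2     # affine rescaling of mediator 1
  e2 <- est(Ms)
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("IV and classical stage-2 fits agree without confounding", {
  cfg <- sim_config(n = 4000, p_total = 60, zeta1 = rep(0, 4),
                    zeta2 = rep(0, 4), censor_rate_target = 0.2, seed = 37)
  d <- generate_dataset(cfg)
  M <- d$covariates[, d$truth$all_structured]
  s1 <- fit_exposure_model(d$covariates[, d$truth$iv_cols], d$exposure)
  lam <- fit_mediator_models(d$exposure, M)$lambda_hat
  g_iv <- fit_outcome_model_iv(s1$instrument_index, M, d$time, d$event)$gamma_hat
  g_cl <- fit_outcome_model_iv(d$exposure, M, d$time, d$event)$gamma_hat
  ind_iv <- unname(lam * g_iv)[1:2]
  ind_cl <- unname(lam * g_cl)[1:2]
  expect_lt(max(abs(ind_iv - ind_cl)), 0.2)
  expect_lt(max(abs(ind_cl - c(0.96, 0.96))), 0.15)
})
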