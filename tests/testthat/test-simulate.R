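test_that("configuration invariants are enforced", {
  expect_error(sim_config(n = 100, gamma_vec = c(1, 2), lambda_vec = 1),
               "same length")
  expect_error(sim_config(n = 1), "at least 2")
  expect_error(sim_config(n = 100, censor_rate_target = 1.2), "in \\(0, 1\\)")
  expect_error(sim_config(n = 100, p_total = 6), "too small")
})

test_that("generation is deterministic under a fixed seed", {
  d1 <- generate_dataset(small_config(seed = 77))
  d2 <- generate_dataset(small_config(seed = 77))
  expect_identical(d1, d2)
  d3 <- generate_dataset(small_config(seed = 78))
  expect_false(identical(d1$covariates, d3$covariates))
})

test_that("dataset structure matches the design", {
  cfg <- small_config(n = 250, p_total = 150, seed = 5)
  d <- generate_dataset(cfg)
  # observed block excludes the 4 withheld confounders
  expect_equal(ncol(d$covariates), cfg$p_total - 4L)
  expect_equal(nrow(d$covariates), 250L)
  expect_false(anyNA(d$covariates))
  expect_true(all(d$event %in% c(0L, 1L)))
  expect_true(all(d$exposure %in% c(0L, 1L)))
  expect_true(all(d$time > 0))
  expect_equal(dim(d$hidden_confounders), c(250L, 4L))
  # exposure prevalence guards against separation
  expect_gt(mean(d$exposure), 0.05)
  expect_lt(mean(d$exposure), 0.95)
  # scenario 1 has exactly two true mediators
  s1 <- generate_dataset(scenario_config("s1", n = 50, seed = 1))
  expect_length(s1$truth$mediator_cols, 2L)
  expect_equal(sort(s1$truth$indirect), c(0, 0, 0.96, 0.96))
  s2 <- generate_dataset(scenario_config("s2", n = 50, seed = 1))
  expect_length(s2$truth$mediator_cols, 4L)
})

test_that("censoring calibration solves the closed-form case", {
  # all linear predictors equal: competing exponentials give
  # target = theta / (theta + r), so theta = r * target / (1 - target)
  lp <- rep(0.7, 400)
  r <- exp(0.7)
  for (target in c(0.2, 0.4, 0.6)) {
    theta <- calibrate_censoring(lp, h0 = 1, target = target)
    expect_equal(theta, r * target / (1 - target), tolerance = 1e-7)
  }
  # monotone in the target
  lp2 <- rnorm(300)
  expect_gt(calibrate_censoring(lp2, 1, 0.6), calibrate_censoring(lp2, 1, 0.2))
  # vanishing target gives a vanishing censoring rate
  expect_lt(calibrate_censoring(lp2, 1, 1e-6), 1e-4)
  expect_error(calibrate_censoring(lp2, 1, 0), "in \\(0, 1\\)")
})

test_that("realized censoring fraction hits the calibrated target", {
  d <- generate_dataset(scenario_config("s1", n = 5000,
                                        censor_rate_target = 0.4, seed = 11))
  expect_lt(abs(mean(1 - d$event) - 0.4), 0.03)
  d2 <- generate_dataset(small_config(n = 5000, p_total = 20, censor = 0.2,
                                      seed = 12,
                                      gamma_vec = c(1.2, 0.8),
                                      lambda_vec = c(0.8, 1.2)))
  expect_lt(abs(mean(1 - d2$event) - 0.2), 0.03)
})

test_that("an all-null model leaves exposure and outcome unrelated", {
  d <- generate_dataset(null_config(n = 10000, seed = 21))
  f <- survival::coxph(survival::Surv(d$time, d$event) ~ d$exposure)
  z <- coef(f) / sqrt(diag(vcov(f)))
  expect_lt(abs(z), 3.5)  # sampling noise around zero
})
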