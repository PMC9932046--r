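# shared fixture: a moderate logistic / survival design with 3 strong
# signals among 30 columns
pen_fixture <- local({
  set.seed(42)
  n <- 400
  x <- matrix(rnorm(n * 30), n, 30)
  eta <- drop(x %*% c(1, -0.8, 0.6, rep(0, 27)))
  y <- rbinom(n, 1, plogis(eta))
  tt <- rexp(n, exp(0.5 * eta))
  cc <- rexp(n, 0.3 * median(exp(0.5 * eta)))
  list(x = x, y = y, time = pmin(tt, cc), event = as.integer(tt <= cc))
})

test_that("the MCP penalty has its closed form and flat region", {
  expect_equal(mcp_penalty(0.5, lambda = 1, gamma = 3),
               1 * 0.5 - 0.25 / 6)  # 0.45833...
  expect_equal(mcp_penalty(0.5, 1, 3), 0.4583333, tolerance = 1e-6)
  # constant gamma * lambda^2 / 2 beyond gamma * lambda
  expect_equal(mcp_penalty(3, 1, 3), 1.5)
  expect_equal(mcp_penalty(100, 1, 3), 1.5)
  expect_equal(mcp_penalty(-100, 1, 3), 1.5)
})

test_that("the null model holds at the head of the path", {
  f <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                              penalty_spec("mcp"))
  expect_true(all(f$beta_path[, 1] == 0))
  fc <- fit_penalized_cox(pen_fixture$x, pen_fixture$time, pen_fixture$event,
                          penalty_spec("mcp"))
  expect_true(all(fc$beta_path[, 1] == 0))
})

test_that("lambda = 0 reproduces the unpenalized maximum likelihood", {
  set.seed(7)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- rbinom(200, 1, plogis(0.5 + x %*% c(0.8, -0.5, 0)))
  f <- fit_penalized_logistic(x, y, penalty_spec("mcp"), lambda = 0)
  g <- glm(y ~ x, family = binomial)
  expect_lt(max(abs(c(f$intercept, f$coefficients) - coef(g))), 1e-5)

  tt <- rexp(200, exp(drop(x %*% c(0.6, -0.4, 0))))
  cc <- rexp(200, 0.45)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  fc <- fit_penalized_cox(x, time, event, penalty_spec("mcp"), lambda = 0)
  cx <- survival::coxph(survival::Surv(time, event) ~ x, ties = "efron")
  expect_lt(max(abs(fc$coefficients - coef(cx))), 1e-4)
})

test_that("the LASSO path agrees with an independent solver", {
  f <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                              penalty_spec("lasso"))
  gn <- glmnet::glmnet(pen_fixture$x, pen_fixture$y, family = "binomial",
                       lambda = f$lambda, thresh = 1e-12)
  for (k in c(10, 40, 80))
    expect_lt(max(abs(as.numeric(coef(gn)[-1, k]) - f$beta_path[, k])), 1e-6)

  fc <- fit_penalized_cox(pen_fixture$x, pen_fixture$time, pen_fixture$event,
                          penalty_spec("lasso"))
  gnc <- glmnet::glmnet(pen_fixture$x,
                        survival::Surv(pen_fixture$time, pen_fixture$event),
                        family = "cox", lambda = fc$lambda, thresh = 1e-12)
  for (k in c(10, 40))
    expect_lt(max(abs(as.numeric(gnc$beta[, k]) - fc$beta_path[, k])), 1e-5)
})

test_that("MCP converges to the LASSO as the concavity flattens", {
  f_l <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                                penalty_spec("lasso"))
  f_m <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                                penalty_spec("mcp", gamma_mcp = 1e6),
                                lambda = f_l$lambda)
  keep <- f_l$converged & f_m$converged
  expect_lt(max(abs(f_m$beta_path[, keep] - f_l$beta_path[, keep])), 1e-4)
})

test_that("KKT conditions hold along the path", {
  for (fam in c("mcp", "lasso")) {
    f <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                                penalty_spec(fam))
    expect_lt(max(penalized_kkt(f, pen_fixture$x, y = pen_fixture$y)), 1e-6)
    fc <- fit_penalized_cox(pen_fixture$x, pen_fixture$time,
                            pen_fixture$event, penalty_spec(fam))
    expect_lt(max(penalized_kkt(fc, pen_fixture$x, time = pen_fixture$time,
                                event = pen_fixture$event)), 1e-6)
  }
})

test_that("selection is invariant to column scaling", {
  f1 <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                               penalty_spec("mcp"))
  xs <- pen_fixture$x
  xs[, 1] <- xs[, 1] * 1000
  xs[, 2] <- xs[, 2] / 500
  f2 <- fit_penalized_logistic(xs, pen_fixture$y, penalty_spec("mcp"))
  expect_identical(f1$support, f2$support)
  expect_equal(f2$coefficients[1] * 1000, f1$coefficients[1], tolerance = 1e-5)
  expect_equal(f2$coefficients[2] / 500, f1$coefficients[2], tolerance = 1e-5)
})

test_that("tuning recovers the true sparse support on a strong design", {
  f <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                              penalty_spec("mcp"))
  expect_true(all(1:3 %in% f$support))
  expect_lte(length(f$support), 8)
  fc <- fit_penalized_cox(pen_fixture$x, pen_fixture$time, pen_fixture$event,
                          penalty_spec("mcp"))
  expect_true(all(1:3 %in% fc$support))
})

test_that("adaptive LASSO and elastic net run to a tuned solution", {
  fa <- fit_penalized_logistic(pen_fixture$x, pen_fixture$y,
                               penalty_spec("alasso"))
  expect_true(all(1:3 %in% fa$support))
  fe <- fit_penalized_cox(pen_fixture$x, pen_fixture$time, pen_fixture$event,
                          penalty_spec("enet", alpha_enet = 0.5))
  expect_true(all(1:3 %in% fe$support))
})

test_that("degenerate inputs error or return empty supports", {
  x <- pen_fixture$x
  expect_error(fit_penalized_cox(x, pen_fixture$time,
                                 rep(0L, nrow(x)), penalty_spec("mcp")),
               "at least one event")
  expect_error(fit_penalized_logistic(x, rep(1, nrow(x)), penalty_spec("mcp")),
               "non-constant")
  xc <- matrix(1, 100, 4)
  tt <- rexp(100); ev <- rbinom(100, 1, 0.7)
  f <- fit_penalized_cox(xc, tt, ev, penalty_spec("mcp"))
  expect_length(f$support, 0)  # flat partial likelihood
})
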