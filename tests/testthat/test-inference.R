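test_that("Sobel test matches its closed form and symmetry", {
  # s = sqrt(0.8^2 * 0.2^2 + 1.2^2 * 0.1^2) = 0.2, z = 0.96 / 0.2 = 4.8
  p <- sobel_test(0.8, 0.1, 1.2, 0.2)
  expect_equal(p, 2 * (1 - pnorm(4.8)))
  expect_equal(p, 1.588655e-06, tolerance = 1e-4)
  # symmetric in the two paths
  expect_identical(sobel_test(0.8, 0.1, 1.2, 0.2),
                   sobel_test(1.2, 0.2, 0.8, 0.1))
  # null point estimate gives p = 1
  expect_identical(sobel_test(0, 0.3, 1.2, 0.2), 1)
  expect_identical(sobel_test(0, 0.3, 0, 0.2), 1)
  expect_error(sobel_test(0.8, 0, 1.2, 0.2), "positive")
})

test_that("joint test is the maximum of the path p-values", {
  expect_identical(joint_test(0.01, 0.04), 0.04)
  expect_identical(joint_test(1, 0), 1)
  expect_identical(joint_test(c(0.2, 0.5), c(0.3, 0.1)), c(0.3, 0.5))
  expect_error(joint_test(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(joint_test(0.1, 1.5), "\\[0, 1\\]")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_identical(bonferroni_adjust(0.04, 10), 0.4)
  expect_identical(bonferroni_adjust(0.9, 5), 1)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni_adjust(p, 7)) >= 0))  # order preserved
  expect_true(all(bonferroni_adjust(p, 7) >= p))        # never decreases
  expect_error(bonferroni_adjust(0.1, 0), "at least 1")
})

test_that("mediator decisions apply the strict threshold", {
  tab <- data.frame(column = 1:3,
                    p_sobel_adj = c(0.049, 0.05, 0.2),
                    p_joint_adj = c(0.01, 0.9, 0.04),
                    boot_significant = c(TRUE, FALSE, NA))
  expect_identical(decide_mediators(tab, 0.05, "sobel"), 1L)
  expect_identical(decide_mediators(tab, 0.05, "joint"), c(1L, 3L))
  expect_identical(decide_mediators(tab, 0.05, "boot"), 1L)
  expect_identical(decide_mediators(tab[0, ], 0.05, "sobel"), integer(0))
  expect_identical(decide_mediators(NULL, 0.05, "sobel"), integer(0))
})

test_that("the bootstrap test is seeded, contained and guarded", {
  fx <- small_fitted_sets(n = 200, seed = 3)
  b1 <- bootstrap_test(fx$data, fx$I2, fx$M1, B = 150, seed = 5)
  b2 <- bootstrap_test(fx$data, fx$I2, fx$M1, B = 150, seed = 5)
  expect_identical(b1, b2)
  b3 <- bootstrap_test(fx$data, fx$I2, fx$M1, B = 150, seed = 6)
  expect_false(identical(b1$ci_low, b3$ci_low))
  # point estimates lie inside their own percentile intervals
  expect_true(all(b1$estimate >= b1$ci_low & b1$estimate <= b1$ci_high))
  expect_error(bootstrap_test(fx$data, fx$I2, fx$M1, B = 50), "at least 100")
  expect_error(bootstrap_test(fx$data, fx$I2, integer(0), B = 200),
               "non-empty")
})

test_that("the joint test is conservative under the composite null", {
  # both paths null: rejection rate at alpha must not exceed alpha
  set.seed(91)
  n <- 120
  rej <- vapply(1:300, function(k) {
    x <- rbinom(n, 1, 0.5)
    m <- rnorm(n)
    tt <- rexp(n)
    ev <- rbinom(n, 1, 0.75)
    pl <- fit_mediator_models(x, cbind(m))$p_lambda
    s2 <- fit_outcome_model_iv(x, cbind(m), tt, ev)
    joint_test(pl, s2$p_gamma) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.05 + 0.02)
})
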