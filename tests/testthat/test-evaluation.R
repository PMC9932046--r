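test_that("FDR and PSR follow their definitions and conventions", {
  s <- compute_fdr_psr(c(1, 2, 9), c(1, 2))
  expect_equal(s$fdr, 1 / 3)
  expect_equal(s$psr, 1)
  # nothing selected: FDR 0 by convention, PSR 0
  s0 <- compute_fdr_psr(integer(0), c(1, 2))
  expect_identical(s0$fdr, 0)
  expect_identical(s0$psr, 0)
  sperf <- compute_fdr_psr(c(4, 5), c(4, 5))
  expect_identical(c(sperf$fdr, sperf$psr), c(0, 1))
})

test_that("FDR and PSR are bounded for arbitrary selections", {
  set.seed(61)
  for (k in 1:100) {
    sel <- sample(50, rpois(1, 4), replace = FALSE)
    tru <- sample(50, 1 + rpois(1, 2), replace = FALSE)
    s <- compute_fdr_psr(sel, tru)
    expect_gte(s$fdr, 0); expect_lte(s$fdr, 1)
    expect_gte(s$psr, 0); expect_lte(s$psr, 1)
    expect_identical(s$tp + s$fn, length(unique(tru)))
  }
})

test_that("Monte-Carlo mean and MSE are computed against the truth", {
  m <- compute_mse(rep(0.96, 5), 0.96)
  expect_identical(m$mse, 0)
  m2 <- compute_mse(c(0.9, 1.02), 0.96)
  expect_equal(m2$mean, 0.96)
  expect_equal(m2$mse, 0.0036)  # both replicates miss by 0.06
  m3 <- compute_mse(c(0.9, 1.02, NA), 0.96)
  expect_identical(m3$n_dropped, 1L)
  expect_error(compute_mse(c(1, NA), 1), "at least 2")
})

test_that("one-replicate benchmark grids emit complete tables", {
  b <- run_selector_benchmark(selectors = c("lasso", "mcp"), n = 200,
                              censor = 0.2, reps = 1, seed = 62)
  expect_identical(nrow(b), 2L)
  expect_true(all(c("selector", "n", "censor", "fdr", "psr") %in% names(b)))
  m <- run_mediation_benchmark(methods = "iv", tests = "sobel", n = 200,
                               censor = 0.2, reps = 2, seed = 63)
  expect_identical(nrow(m$cells), 1L)
  expect_identical(nrow(m$estimates), 4L)  # one row per structured mediator
  expect_true(all(m$cells$fdr >= 0 & m$cells$fdr <= 1))
})
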