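#' Sobel test of a mediated (indirect) effect
#'
#' Normal-approximation test of `H0: lambda * gamma = 0` using the
#' delta-method standard error `sqrt(lambda^2 S_gamma^2 + gamma^2
#' S_lambda^2)`; the p-value is `2 (1 - Phi(|lambda gamma| / s))`. The test
#' is symmetric in the two paths. When both point estimates are zero the
#' statistic is taken as 0 (p = 1).
#'
#' @param lambda_hat,s_lambda Exposure-to-mediator estimate and SE.
#' @param gamma_hat,s_gamma Mediator-to-outcome estimate and SE.
#' @return Two-sided p-value (vectorised over mediators).
#' @export
#' @examples
#' sobel_test(0.8, 0.1, 1.2, 0.2)  # z = 4.8
sobel_test <- function(lambda_hat, s_lambda, gamma_hat, s_gamma) {
  if (any(s_lambda <= 0) || any(s_gamma <= 0))
    stop("standard errors must be positive")
  s <- sqrt(lambda_hat^2 * s_gamma^2 + gamma_hat^2 * s_lambda^2)
  z <- ifelse(s > 0, abs(lambda_hat * gamma_hat) / s, 0)
  2 * (1 - pnorm(z))
}

#' Joint significance test of a mediated effect
#'
#' Declares mediation only when both path null hypotheses are rejected; the
#' composite p-value is the maximum of the two path p-values.
#'
#' @param p_lambda,p_gamma Path p-values in `[0, 1]`.
#' @return `pmax(p_lambda, p_gamma)` (vectorised).
#' @export
joint_test <- function(p_lambda, p_gamma) {
  if (any(p_lambda < 0 | p_lambda > 1) || any(p_gamma < 0 | p_gamma > 1))
    stop("p-values must lie in [0, 1]")
  pmax(p_lambda, p_gamma)
}

#' Bonferroni adjustment
#'
#' `min(p * q, 1)` elementwise, where `q` is the number of tests performed
#' (by default the number of candidate mediators actually tested).
#'
#' @param p_raw Raw p-values.
#' @param q Number of comparisons (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_raw, q) {
  if (q < 1) stop("`q` must be at least 1")
  pmin(p_raw * q, 1)
}

#' Percentile-bootstrap test of the per-mediator indirect effects
#'
#' Resamples subjects with replacement, re-estimates the stage-1 exposure
#' model, the stage-2 Cox outcome model and the per-mediator OLS models on
#' the *fixed* selected sets (no re-selection), and forms percentile
#' confidence intervals of each `lambda_hat * gamma_hat`. A mediator is
#' declared significant when its interval excludes zero.
#'
#' @param data A `mediation_data`.
#' @param I2 Candidate instrument columns (ignored when
#'   `method = "classical"`).
#' @param M1 Candidate mediator columns (non-empty).
#' @param B Number of bootstrap replicates (>= 100).
#' @param alpha Significance level of the `1 - alpha` percentile interval.
#' @param seed Optional seed for reproducible resampling.
#' @param method `"iv"` (instrumented exposure index in stage 2) or
#'   `"classical"` (observed exposure).
#' @return A data.frame with one row per mediator: point estimate (full
#'   data), `ci_low`, `ci_high`, `significant`, number of successful
#'   replicates.
#' @export
bootstrap_test <- function(data, I2, M1, B = 1000, alpha = 0.05,
                           seed = NULL, method = c("iv", "classical")) {
  method <- match.arg(method)
  if (B < 100) stop("`B` must be at least 100")
  if (!length(M1)) stop("`M1` must be non-empty")
  if (method == "iv" && !length(I2)) stop("`I2` must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  n <- length(data$time)
  Mmat <- data$covariates[, M1, drop = FALSE]
  Zmat <- if (method == "iv")
    cbind(1, data$covariates[, I2, drop = FALSE]) else NULL
  x <- data$exposure
  time <- data$time
  event <- as.integer(data$event)
  q <- length(M1)
  est <- matrix(NA_real_, B, q)
  ctrl <- coxph.control()
  fail <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    ok <- try({
      xb <- x[idx]
      if (var(xb) == 0) stop("degenerate resample")
      proxy <- if (method == "iv") {
        g <- suppressWarnings(glm.fit(Zmat[idx, , drop = FALSE], xb,
                                      family = binomial()))
        drop(Zmat[idx, , drop = FALSE] %*% g$coefficients)
      } else xb
      Mb <- Mmat[idx, , drop = FALSE]
      xx <- cbind(proxy, Mb)
      cfit <- coxph.fit(xx, Surv(time[idx], event[idx]),
                        strata = NULL, offset = NULL, init = NULL,
                        control = ctrl, weights = NULL, method = "efron",
                        rownames = NULL)
      gam <- cfit$coefficients[-1]
      xbar <- mean(xb)
      lam <- drop(crossprod(xb - xbar, Mb)) / sum((xb - xbar)^2)
      est[b, ] <- lam * gam
      TRUE
    }, silent = TRUE)
    if (inherits(ok, "try-error") || anyNA(est[b, ])) fail <- fail + 1L
  }
  if (fail > 0.1 * B)
    stop(sprintf("bootstrap failed in %d of %d replicates (%.1f%%)",
                 fail, B, 100 * fail / B))
  # full-data point estimates on the same fixed sets
  proxy0 <- if (method == "iv") {
    g <- suppressWarnings(glm.fit(Zmat, x, family = binomial()))
    drop(Zmat %*% g$coefficients)
  } else x
  cfit0 <- coxph.fit(cbind(proxy0, Mmat), Surv(time, event), strata = NULL,
                     offset = NULL, init = NULL, control = ctrl,
                     weights = NULL, method = "efron", rownames = NULL)
  xbar <- mean(x)
  lam0 <- drop(crossprod(x - xbar, Mmat)) / sum((x - xbar)^2)
  point <- lam0 * cfit0$coefficients[-1]
  ci <- apply(est, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              na.rm = TRUE)
  data.frame(mediator = colnames(Mmat) %||% paste0("M", M1),
             column = M1, estimate = unname(point),
             ci_low = ci[1, ], ci_high = ci[2, ],
             significant = ci[1, ] > 0 | ci[2, ] < 0,
             boot_B = B - fail, row.names = NULL)
}

#' Declare significant mediators
#'
#' For p-value-based tests, returns the mediators whose *adjusted* p-value
#' is strictly below `alpha`; for the bootstrap, those whose percentile
#' interval excludes zero.
#'
#' @param results A `mediation_tests` data.frame (see [run_proposed()]), or
#'   any data.frame with the relevant columns.
#' @param alpha Significance level.
#' @param test Which test's decision to use: `"sobel"`, `"joint"` or
#'   `"boot"`.
#' @return The `column` values (covariate indices) of the declared
#'   mediators; integer(0) for empty input.
#' @export
decide_mediators <- function(results, alpha = 0.05,
                             test = c("sobel", "joint", "boot")) {
  test <- match.arg(test)
  if (is.null(results) || !nrow(results)) return(integer(0))
  keep <- switch(test,
                 sobel = results$p_sobel_adj < alpha,
                 joint = results$p_joint_adj < alpha,
                 boot = results$boot_significant)
  keep[is.na(keep)] <- FALSE
  results$column[keep]
}
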