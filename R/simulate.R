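#' Simulation configuration for confounded survival mediation data
#'
#' Describes one synthetic study condition: a binary exposure driven by two
#' continuous instruments and four withheld confounders, normally distributed
#' mediators downstream of the exposure, and an exponential-baseline Cox
#' outcome whose hazard loads on the exposure, the structured mediators and
#' the confounders. The confounders are generated but withheld from the
#' observed covariate block, emulating unmeasured confounding in an
#' observational epigenetic study.
#'
#' @param n Sample size.
#' @param p_total Total covariate pool size, counting the 4 withheld
#'   confounders. The observed block has `p_total - 4` columns: the 2
#'   instruments, the structured mediators, and iid N(0,1) null mediators.
#' @param gamma_vec Mediator-to-outcome log-hazard coefficients for the
#'   structured mediator columns (zeros implied beyond its length).
#' @param lambda_vec Exposure-to-mediator coefficients, same length as
#'   `gamma_vec`. Mediator `i` is a true mediator iff
#'   `lambda_vec[i] * gamma_vec[i] != 0`.
#' @param beta Direct exposure effect on the log hazard.
#' @param zeta1,zeta2 Confounder coefficients on the outcome and on the
#'   exposure log-odds (length 4).
#' @param eta Instrument-to-exposure log-odds coefficients (length 2).
#' @param a,c,d Intercepts of the outcome, mediator, and exposure models.
#' @param sd_iv Standard deviations of the two (independent normal)
#'   instruments.
#' @param sd_conf Standard deviations of the two continuous confounders; the
#'   other two confounders are Bernoulli with success probabilities `p_bern`.
#' @param p_bern Success probabilities of the two binary confounders.
#' @param mediator_noise_sd Standard deviation of the mediator error term.
#' @param baseline_hazard Exponential baseline hazard rate h0.
#' @param censor_rate_target Expected fraction of censored observations; the
#'   exponential censoring rate is calibrated to hit it.
#' @param frailty_sd Standard deviation of an optional log-normal frailty in
#'   the hazard exponent (0 = proportional hazards exactly; nonzero only for
#'   sensitivity runs).
#' @param seed Integer seed making [generate_dataset()] deterministic.
#'
#' @return An object of class `medsim_config`.
#' @seealso [scenario_config()] for the two benchmark scenarios,
#'   [generate_dataset()].
#' @export
#' @examples
#' cfg <- sim_config(n = 100, p_total = 50, gamma_vec = c(1.2, 0.8),
#'                   lambda_vec = c(0.8, 1.2), seed = 1)
sim_config <- function(n, p_total = 1000,
                       gamma_vec = c(1.2, 0.8, 1.5, 0),
                       lambda_vec = c(0.8, 1.2, 0, 1.5),
                       beta = 1.5,
                       zeta1 = c(0.4, 0.5, 0.6, 0.7),
                       zeta2 = c(0.4, 0.5, 0.6, 0.7),
                       eta = c(1.0, 1.5),
                       a = 0, c = 0, d = 0,
                       sd_iv = c(0.9, 1.1),
                       sd_conf = c(0.8, 1.2),
                       p_bern = c(0.4, 0.6),
                       mediator_noise_sd = 1,
                       baseline_hazard = 1,
                       censor_rate_target = 0.2,
                       frailty_sd = 0,
                       seed = NULL) {
  if (length(gamma_vec) != length(lambda_vec))
    stop("`gamma_vec` and `lambda_vec` must have the same length")
  if (n < 2) stop("`n` must be at least 2")
  if (censor_rate_target <= 0 || censor_rate_target >= 1)
    stop("`censor_rate_target` must lie in (0, 1)")
  if (length(zeta1) != 4L || length(zeta2) != 4L)
    stop("`zeta1` and `zeta2` must have length 4")
  n_med <- length(gamma_vec)
  p_obs <- p_total - 4L  # confounders withheld; exposure is its own column
  if (p_obs < length(eta) + n_med)
    stop("`p_total` too small for the instruments and structured mediators")
  structure(
    list(n = as.integer(n), p_total = as.integer(p_total),
         gamma_vec = gamma_vec, lambda_vec = lambda_vec, beta = beta,
         zeta1 = zeta1, zeta2 = zeta2, eta = eta, a = a, c = c, d = d,
         sd_iv = sd_iv, sd_conf = sd_conf, p_bern = p_bern,
         mediator_noise_sd = mediator_noise_sd,
         baseline_hazard = baseline_hazard,
         censor_rate_target = censor_rate_target,
         frailty_sd = frailty_sd, seed = seed),
    class = "medsim_config")
}

#' Benchmark scenario configurations
#'
#' Preset coefficient layouts used throughout the simulation benchmarks:
#' scenario `"s1"` has 1,000 total covariates with two true mediators
#' (indirect effects 0.96 and 0.96); scenario `"s2"` has 3,000 covariates
#' with four true mediators (0.96, 0.96, -0.96, -0.96).
#'
#' @param scenario `"s1"` or `"s2"`.
#' @param n Sample size.
#' @param censor_rate_target Target censoring fraction.
#' @param seed Optional seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A `medsim_config`.
#' @export
scenario_config <- function(scenario = c("s1", "s2"), n,
                            censor_rate_target = 0.2, seed = NULL, ...) {
  scenario <- match.arg(scenario)
  if (scenario == "s1") {
    sim_config(n = n, p_total = 1000,
               gamma_vec = c(1.2, 0.8, 1.5, 0),
               lambda_vec = c(0.8, 1.2, 0, 1.5),
               censor_rate_target = censor_rate_target, seed = seed, ...)
  } else {
    sim_config(n = n, p_total = 3000,
               gamma_vec = c(1.2, 0.8, -1.2, 1.2, 1.5, 0),
               lambda_vec = c(0.8, 1.2, 0.8, -0.8, 0, 1.5),
               censor_rate_target = censor_rate_target, seed = seed, ...)
  }
}

expit <- function(x) 1 / (1 + exp(-x))

#' Calibrate an exponential censoring rate to a target censoring fraction
#'
#' Survival times are conditionally exponential with rate
#' `h0 * exp(lp)` given the linear predictor `lp`, and censoring times are
#' exponential with rate `theta` drawn independently. The expected censoring
#' fraction is then `mean(theta / (theta + h0 * exp(lp)))`; this function
#' solves that expression for `theta` by root-finding over the empirical
#' distribution of linear predictors.
#'
#' @param linear_predictors Realized hazard linear predictors (one per
#'   subject).
#' @param h0 Baseline hazard rate.
#' @param target Desired expected censoring fraction, in (0, 1).
#' @return The exponential censoring rate `theta`.
#' @export
#' @examples
#' # equal linear predictors reduce to the two-exponential closed form
#' calibrate_censoring(rep(0, 100), h0 = 1, target = 0.25)  # 1/3
calibrate_censoring <- function(linear_predictors, h0, target) {
  if (target <= 0 || target >= 1) stop("`target` must lie in (0, 1)")
  if (h0 <= 0) stop("`h0` must be positive")
  rates <- h0 * exp(pmin(pmax(linear_predictors, -200), 200))
  f <- function(theta) mean(theta / (theta + rates)) - target
  hi <- max(rates)
  # f is increasing in theta with limits -target and 1 - target
  for (k in 1:60) {
    if (f(hi) >= 0) break
    hi <- hi * 10
  }
  if (f(hi) < 0)
    stop("censoring calibration failed: achievable rate at upper bracket = ",
         signif(f(hi) + target, 3), " < target ", target)
  uniroot(f, lower = 0, upper = hi, tol = 1e-10)$root
}

#' Generate a synthetic confounded mediation dataset
#'
#' Draws instruments, withheld confounders, a binary exposure from a logistic
#' model on both, normally distributed mediators downstream of the exposure,
#' and an exponential-baseline Cox outcome by inverse-transform sampling,
#' with independent exponential censoring calibrated to the configured
#' censoring fraction. Observed covariate columns are shuffled so that column
#' position carries no information; the true instrument and mediator column
#' indices are recorded in `truth`.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `mediation_data`: a list with `time`, `event`,
#'   `exposure`, `covariates` (matrix with columns `V0001`, ...),
#'   `hidden_confounders` (n x 4, withheld from analysis), and `truth`
#'   (`iv_cols`, `mediator_cols`, `all_structured`, per-mediator generating
#'   `lambda`, `gamma`, `indirect`).
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "medsim_config"))
  seed <- if (is.null(seed)) config$seed else seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  n_med <- length(config$gamma_vec)
  p_obs <- config$p_total - 4L
  n_noise <- p_obs - 2L - n_med

  Z <- cbind(rnorm(n, 0, config$sd_iv[1]), rnorm(n, 0, config$sd_iv[2]))
  L <- cbind(rnorm(n, 0, config$sd_conf[1]), rnorm(n, 0, config$sd_conf[2]),
             rbinom(n, 1, config$p_bern[1]), rbinom(n, 1, config$p_bern[2]))
  pX <- expit(config$d + drop(Z %*% config$eta) + drop(L %*% config$zeta2))
  X <- rbinom(n, 1, pX)

  M <- matrix(rnorm(n * n_med, 0, config$mediator_noise_sd), n, n_med)
  M <- M + config$c + outer(X, config$lambda_vec)
  noise <- if (n_noise > 0)
    matrix(rnorm(n * n_noise), n, n_noise) else matrix(0, n, 0)

  lp <- config$a + config$beta * X + drop(M %*% config$gamma_vec) +
    drop(L %*% config$zeta1)
  if (config$frailty_sd > 0) lp <- lp + rnorm(n, 0, config$frailty_sd)
  T_lat <- -log(runif(n)) / (config$baseline_hazard * exp(lp))
  theta <- calibrate_censoring(lp, config$baseline_hazard,
                               config$censor_rate_target)
  C_lat <- rexp(n, rate = theta)
  time <- pmin(T_lat, C_lat)
  event <- as.integer(T_lat <= C_lat)

  covariates <- cbind(Z, M, noise)
  perm <- sample.int(p_obs)
  covariates <- covariates[, order(perm), drop = FALSE]
  # column k of `covariates` held original column order(perm)[k]; invert:
  pos <- integer(p_obs)
  pos[order(perm)] <- seq_len(p_obs)  # original index -> new position
  colnames(covariates) <- sprintf("V%04d", seq_len(p_obs))

  med_cols <- pos[2L + seq_len(n_med)]
  truth <- list(
    iv_cols = pos[1:2],  # generation order: (Z1, Z2), pairing with eta kept
    mediator_cols = sort(med_cols[config$lambda_vec * config$gamma_vec != 0]),
    all_structured = med_cols,
    lambda = config$lambda_vec,
    gamma = config$gamma_vec,
    indirect = config$lambda_vec * config$gamma_vec,
    censor_theta = theta,
    config = config)

  structure(list(time = time, event = event, exposure = X,
                 covariates = covariates, hidden_confounders = L,
                 truth = truth),
            class = "mediation_data")
}

#' @export
print.mediation_data <- function(x, ...) {
  cat("<mediation_data> n =", length(x$time),
      " observed covariates =", ncol(x$covariates), "\n")
  cat("  events:", sum(x$event), sprintf("(censoring %.1f%%)",
      100 * mean(1 - x$event)), " P(X=1) =", round(mean(x$exposure), 3), "\n")
  if (!is.null(x$truth))
    cat("  truth: IV cols {", paste(x$truth$iv_cols, collapse = ", "),
        "}, true mediator cols {",
        paste(x$truth$mediator_cols, collapse = ", "), "}\n")
  invisible(x)
}
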