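#' Partition selected variables into candidate instruments
#'
#' Variables selected for the exposure but not for the outcome are the
#' candidate instruments: `I2 = I1 \ M1`. Columns selected by both fits are
#' treated as mediators and removed from the instrument set.
#'
#' @param I1 Columns selected by the penalized logistic (exposure) fit.
#' @param M1 Columns selected by the penalized Cox (outcome) fit.
#' @return Integer vector `I2`.
#' @export
partition_candidates <- function(I1, M1) {
  I2 <- sort(setdiff(I1, M1))
  if (!length(I2))
    stop("no valid instruments: every exposure-selected column was also ",
         "outcome-selected; consider a sparser mediator penalty or ",
         "supplying instruments explicitly")
  I2
}

.drop_zero_var <- function(x, what) {
  s <- apply(x, 2, sd)
  bad <- which(!is.finite(s) | s < 1e-10)
  if (length(bad)) {
    warning("dropping ", length(bad), " zero-variance ", what, " column(s): ",
            paste(colnames(x)[bad], collapse = ", "))
    x <- x[, -bad, drop = FALSE]
  }
  x
}

#' Stage-1 exposure model on the candidate instruments
#'
#' Unpenalized logistic maximum likelihood of the binary exposure on the
#' candidate instruments only (the unmeasured confounders are, by
#' construction, unavailable). The per-subject fitted linear predictor is
#' the instrument index substituted for the exposure in stage 2.
#'
#' @param Z_cols Matrix of candidate instrument columns.
#' @param exposure Binary 0/1 exposure.
#' @return List with `d_hat` (intercept), `eta_hat`, `se_eta`,
#'   `instrument_index` (fitted linear predictor, intercept included) and
#'   `fitted_prob`.
#' @export
fit_exposure_model <- function(Z_cols, exposure) {
  Z_cols <- as.matrix(Z_cols)
  if (length(unique(exposure)) < 2) stop("`exposure` must be non-constant")
  if (is.null(colnames(Z_cols)))
    colnames(Z_cols) <- paste0("z", seq_len(ncol(Z_cols)))
  Z_cols <- .drop_zero_var(Z_cols, "instrument")
  if (!ncol(Z_cols)) stop("no non-degenerate instrument columns remain")
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, Z_cols), exposure, family = binomial()))
  cf <- fit$coefficients
  if (!fit$converged || any(abs(cf[-1]) > 15))
    stop("stage-1 logistic fit did not converge (possible complete ",
         "separation); consider a penalized refit of the exposure model")
  eta_lp <- drop(cbind(1, Z_cols) %*% cf)
  w <- fit$weights
  XtWX <- crossprod(cbind(1, Z_cols) * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  list(d_hat = unname(cf[1]), eta_hat = cf[-1],
       se_eta = setNames(se[-1], names(cf[-1])),
       instrument_index = eta_lp, fitted_prob = expit(eta_lp))
}

#' Stage-2 Cox outcome model with the instrumented exposure
#'
#' Unpenalized Cox partial-likelihood fit (Efron ties) of the survival
#' outcome on the instrument index and the candidate mediator columns.
#' `beta_hat` is the log-hazard coefficient on the index as supplied (no
#' two-stage rescaling); `gamma_hat` are the mediator coefficients with
#' Wald standard errors from the observed information.
#'
#' @param instrument_index Per-subject exposure proxy (stage-1 linear
#'   predictor, fitted probability, or the observed exposure for the
#'   classical comparator).
#' @param M1_cols Matrix of candidate mediator columns (may have 0 columns).
#' @param time,event Survival outcome.
#' @return List with `beta_hat`, `se_beta`, `gamma_hat`, `se_gamma`,
#'   `p_gamma` (Wald), `hr` table and the `coxph` fit.
#' @export
fit_outcome_model_iv <- function(instrument_index, M1_cols, time, event) {
  if (sum(event) < 1) stop("need at least one event")
  if (any(!is.finite(instrument_index))) stop("`instrument_index` must be finite")
  M1_cols <- as.matrix(M1_cols)
  if (ncol(M1_cols) && is.null(colnames(M1_cols)))
    colnames(M1_cols) <- paste0("m", seq_len(ncol(M1_cols)))
  med_names <- colnames(M1_cols)
  if (ncol(M1_cols)) M1_cols <- .drop_zero_var(M1_cols, "mediator")
  xx <- cbind(exposure_index = instrument_index, M1_cols)
  df <- data.frame(time = time, event = event)
  fit <- coxph(Surv(time, event) ~ xx, data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0))
    stop("stage-2 Cox fit did not converge")
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  names(cf) <- names(se) <- colnames(xx)
  kept <- colnames(M1_cols)
  gamma_hat <- se_gamma <- setNames(rep(NA_real_, length(med_names)), med_names)
  gamma_hat[kept] <- cf[kept]
  se_gamma[kept] <- se[kept]
  # dropped zero-variance mediators contribute nothing: coefficient 0, z = 0
  gamma_hat[is.na(gamma_hat)] <- 0
  se_gamma[is.na(se_gamma)] <- Inf
  p_gamma <- 2 * pnorm(-abs(gamma_hat / se_gamma))
  hr <- data.frame(term = colnames(xx), estimate = cf, se = se,
                   z = cf / se, p = 2 * pnorm(-abs(cf / se)),
                   hr = exp(cf),
                   hr_lower = exp(cf - qnorm(0.975) * se),
                   hr_upper = exp(cf + qnorm(0.975) * se),
                   row.names = NULL)
  list(beta_hat = unname(cf["exposure_index"]),
       se_beta = unname(se["exposure_index"]),
       gamma_hat = gamma_hat, se_gamma = se_gamma, p_gamma = p_gamma,
       hr = hr, fit = fit)
}

#' Per-mediator exposure-to-mediator models
#'
#' Simple ordinary-least-squares regressions of each candidate mediator on
#' the observed exposure, vectorised across mediators: slope `lambda_hat`,
#' intercept `c_hat`, residual-based standard error and a normal-theory
#' p-value per mediator.
#'
#' @param exposure Binary 0/1 exposure (non-constant).
#' @param M1_cols Matrix of candidate mediator columns.
#' @return List with `c_hat`, `lambda_hat`, `se_lambda`, `p_lambda`.
#' @export
fit_mediator_models <- function(exposure, M1_cols) {
  M1_cols <- as.matrix(M1_cols)
  x <- as.numeric(exposure)
  if (var(x) == 0) stop("`exposure` must be non-constant")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  mbar <- colMeans(M1_cols)
  sxy <- drop(crossprod(x - xbar, M1_cols))
  lambda_hat <- sxy / sxx
  c_hat <- mbar - lambda_hat * xbar
  res <- M1_cols - outer(rep(1, n), c_hat) - outer(x, lambda_hat)
  rss <- colSums(res^2)
  se_lambda <- sqrt(rss / (n - 2) / sxx)
  tstat <- lambda_hat / se_lambda
  p_lambda <- 2 * pnorm(-abs(tstat))
  nm <- colnames(M1_cols)
  list(c_hat = setNames(c_hat, nm), lambda_hat = setNames(lambda_hat, nm),
       se_lambda = setNames(se_lambda, nm), p_lambda = setNames(p_lambda, nm))
}
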