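#' Penalty specification for the coordinate-descent solvers
#'
#' @param family Penalty family: `"mcp"` (minimax concave penalty, the
#'   default selector of the pipeline), `"lasso"`, `"alasso"` (adaptive
#'   LASSO with weights from a small-ridge initial fit), or `"enet"`
#'   (elastic net).
#' @param gamma_mcp MCP concavity parameter (> 1). Larger values approach
#'   the LASSO.
#' @param alpha_enet Elastic-net mixing weight in (0, 1]; 1 is the LASSO.
#' @param nlambda Number of penalty strengths on the path.
#' @param lambda_min_ratio Smallest path value as a fraction of the
#'   data-derived `lambda_max`; defaults to 0.01 for logistic fits and 0.05
#'   for Cox fits.
#' @param tuning Path tuning criterion: `"bic"` (default) or `"cv10"`
#'   (10-fold cross-validated deviance).
#' @param nfolds Folds for `"cv10"`.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("mcp", "lasso", "alasso", "enet"),
                         gamma_mcp = 3, alpha_enet = 0.5, nlambda = 100,
                         lambda_min_ratio = NULL,
                         tuning = c("bic", "cv10"), nfolds = 10) {
  family <- match.arg(family)
  tuning <- match.arg(tuning)
  if (gamma_mcp <= 1) stop("`gamma_mcp` must exceed 1")
  if (alpha_enet <= 0 || alpha_enet > 1) stop("`alpha_enet` must be in (0, 1]")
  structure(list(family = family, gamma_mcp = gamma_mcp,
                 alpha_enet = alpha_enet, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, tuning = tuning,
                 nfolds = as.integer(nfolds)),
            class = "penalty_spec")
}

# effective (alpha, gamma, pen code) triple for the C++ solver
.pen_code <- function(spec) {
  switch(spec$family,
         mcp = list(pen = 1L, alpha = 1, gamma = spec$gamma_mcp),
         lasso = list(pen = 0L, alpha = 1, gamma = Inf),
         alasso = list(pen = 0L, alpha = 1, gamma = Inf),
         enet = list(pen = 0L, alpha = spec$alpha_enet, gamma = Inf))
}

# adaptive-lasso penalty factors from a small-ridge initial fit
# (the ridge stabilises the initial estimate when p is close to n)
.alasso_weights <- function(x, y, family, time = NULL, event = NULL) {
  if (family == "binomial") {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0, nlambda = 30)
    b <- as.numeric(fit$beta[, ncol(fit$beta)])
  } else {
    fit <- glmnet::glmnet(x, survival::Surv(time, event), family = "cox",
                          alpha = 0, nlambda = 30)
    b <- as.numeric(fit$beta[, ncol(fit$beta)])
  }
  w <- 1 / pmax(abs(b), 1e-6)
  w <- pmin(w, 1e6)
  w * length(w) / sum(w)  # rescale so the factors average to 1
}

.standardize <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2)
  keep <- which(s > 1e-10)
  xs <- sweep(x[, keep, drop = FALSE], 2, mu[keep], "-")
  xs <- sweep(xs, 2, s[keep], "/")
  list(x = xs, mu = mu, s = s, keep = keep)
}

.lambda_path <- function(grad0, pf, alpha, nlambda, ratio) {
  lmax <- max(abs(grad0) / (pf * alpha), na.rm = TRUE)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  lmax <- lmax * 1.0001  # guarantee the null model at the path head
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

.finalize_penfit <- function(fit, std, p_in, lambda, spec, pf, n, family,
                             loglik_null, cn) {
  nl <- length(lambda)
  beta_std <- matrix(0, p_in, nl)
  beta_std[std$keep, ] <- fit$beta
  beta_orig <- beta_std / ifelse(std$s > 1e-10, std$s, 1)
  df <- colSums(beta_std != 0)
  bic <- -2 * fit$loglik + df * log(n)
  conv <- as.logical(fit$converged)
  cand <- which(conv)
  if (!length(cand)) cand <- seq_len(nl)
  structure(list(
    family = family, spec = spec, lambda = lambda, penalty_factor = pf,
    beta_path = beta_orig, beta0_path = fit$beta0, df = df,
    loglik = fit$loglik, loglik_null = loglik_null, bic = bic,
    converged = conv, iter = fit$iter, standardization = std,
    colnames = cn, n = n), class = "penfit")
}

.tune_penfit <- function(pf_obj, cv_dev = NULL) {
  crit <- if (is.null(cv_dev)) pf_obj$bic else cv_dev
  crit[!pf_obj$converged] <- Inf
  idx <- which.min(crit)
  pf_obj$lambda_index <- idx
  pf_obj$lambda_selected <- pf_obj$lambda[idx]
  b <- pf_obj$beta_path[, idx]
  names(b) <- pf_obj$colnames
  pf_obj$coefficients <- b
  pf_obj$intercept <- if (!is.null(pf_obj$beta0_path)) pf_obj$beta0_path[idx] else 0
  pf_obj$support <- which(b != 0)
  pf_obj$criterion <- crit
  pf_obj
}

#' Penalized logistic regression along a decreasing penalty path
#'
#' Coordinate descent with IRLS outer loops, warm starts, an unpenalized
#' intercept, and internal standardization (coefficients are reported on the
#' original scale and selection is invariant to column scaling). The MCP
#' concavity is rescaled per coordinate by the IRLS curvature so every
#' one-dimensional update is strictly convex.
#'
#' @param x Numeric predictor matrix.
#' @param y Binary 0/1 response (non-constant).
#' @param spec A [penalty_spec()].
#' @param lambda Optional user path (decreasing); derived from the data when
#'   `NULL`. `lambda = 0` gives the unpenalized maximum-likelihood fit.
#' @return An object of class `penfit`: coefficient path on the original
#'   scale, selected `coefficients`/`support`/`lambda_selected` under the
#'   tuning criterion, per-`lambda` BIC, log-likelihoods and convergence
#'   flags.
#' @export
fit_penalized_logistic <- function(x, y, spec = penalty_spec(),
                                   lambda = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("`y` must be a non-constant binary vector")
  if (!all(y %in% c(0, 1))) stop("`y` must be coded 0/1")
  n <- nrow(x)
  std <- .standardize(x)
  p <- ncol(std$x)
  if (p == 0) stop("all predictor columns are constant")
  pc <- .pen_code(spec)
  pf <- if (spec$family == "alasso")
    .alasso_weights(std$x, y, "binomial") else rep(1, p)
  if (is.null(lambda)) {
    grad0 <- drop(crossprod(std$x, y - mean(y))) / n
    ratio <- if (is.null(spec$lambda_min_ratio)) 0.01 else spec$lambda_min_ratio
    lambda <- .lambda_path(grad0, pf, pc$alpha, spec$nlambda, ratio)
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  gam <- if (is.finite(pc$gamma)) pc$gamma else 1e12
  fit <- cd_logistic_path(std$x, y, lambda, pc$alpha, gam, pf, pc$pen,
                          1e-7, 50L, 300L)
  pbar <- mean(y)
  ll0 <- n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  out <- .finalize_penfit(fit, std, ncol(x), lambda, spec, pf, n,
                          "binomial", ll0,
                          colnames(x) %||% paste0("x", seq_len(ncol(x))))
  # intercept back on the original scale
  adj <- drop(crossprod(out$beta_path, std$mu))
  out$beta0_path <- fit$beta0 - adj
  cv <- if (spec$tuning == "cv10")
    .cv_deviance(x, y, NULL, NULL, spec, lambda, "binomial") else NULL
  .tune_penfit(out, cv)
}

#' Penalized Cox regression along a decreasing penalty path
#'
#' Coordinate descent on the Efron-ties partial likelihood with IRLS outer
#' loops, warm starts and internal standardization; same path and tuning
#' contract as [fit_penalized_logistic()].
#'
#' @param x Numeric predictor matrix.
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators (at least one event).
#' @param spec A [penalty_spec()].
#' @param lambda Optional user path; `lambda = 0` gives the unpenalized
#'   partial-likelihood fit.
#' @return A `penfit` (no intercept: the Cox baseline absorbs it).
#' @export
fit_penalized_cox <- function(x, time, event, spec = penalty_spec(),
                              lambda = NULL) {
  x <- as.matrix(x)
  if (any(time <= 0)) stop("`time` must be positive")
  event <- as.integer(event)
  if (sum(event) < 1) stop("need at least one event")
  n <- nrow(x)
  ord <- order(time)
  std <- .standardize(x[ord, , drop = FALSE])
  p <- ncol(std$x)
  ts <- as.numeric(time[ord])
  ev <- event[ord]
  pc <- .pen_code(spec)
  if (p == 0) {
    # flat partial likelihood: empty support at every lambda
    ll <- cox_wz(rep(0, n), ts, ev)$loglik
    lambda <- lambda %||% 1
    out <- structure(list(
      family = "cox", spec = spec, lambda = lambda,
      penalty_factor = numeric(0),
      beta_path = matrix(0, ncol(x), length(lambda)), beta0_path = NULL,
      df = rep(0, length(lambda)), loglik = rep(ll, length(lambda)),
      loglik_null = ll, bic = rep(-2 * ll, length(lambda)),
      converged = rep(TRUE, length(lambda)), iter = rep(0L, length(lambda)),
      standardization = list(keep = integer(0)),
      colnames = colnames(x) %||% character(ncol(x)), n = n),
      class = "penfit")
    return(.tune_penfit(out))
  }
  pf <- if (spec$family == "alasso")
    .alasso_weights(std$x, NULL, "cox", ts, ev) else rep(1, p)
  null_wz <- cox_wz(rep(0, n), ts, ev)
  if (is.null(lambda)) {
    grad0 <- drop(crossprod(std$x, null_wz$grad)) / n
    ratio <- if (is.null(spec$lambda_min_ratio)) 0.05 else spec$lambda_min_ratio
    lambda <- .lambda_path(grad0, pf, pc$alpha, spec$nlambda, ratio)
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  gam <- if (is.finite(pc$gamma)) pc$gamma else 1e12
  fit <- cd_cox_path(std$x, ts, ev, lambda, pc$alpha, gam, pf, pc$pen,
                     1e-7, 50L, 300L)
  fit$beta0 <- NULL
  out <- .finalize_penfit(fit, std, ncol(x), lambda, spec, pf, n, "cox",
                          null_wz$loglik,
                          colnames(x) %||% paste0("x", seq_len(ncol(x))))
  out$beta0_path <- NULL
  out$sorted <- list(time = ts, event = ev)
  cv <- if (spec$tuning == "cv10")
    .cv_deviance(x, NULL, time, event, spec, lambda, "cox") else NULL
  .tune_penfit(out, cv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 10-fold cross-validated deviance over a fixed lambda path
.cv_deviance <- function(x, y, time, event, spec, lambda, family) {
  n <- nrow(x)
  spec$tuning <- "bic"  # inner fits must not recurse into CV
  folds <- sample(rep_len(seq_len(spec$nfolds), n))
  dev <- matrix(NA_real_, spec$nfolds, length(lambda))
  for (k in seq_len(spec$nfolds)) {
    tr <- folds != k
    if (family == "binomial") {
      f <- try(fit_penalized_logistic(x[tr, , drop = FALSE], y[tr], spec,
                                      lambda = lambda), silent = TRUE)
      if (inherits(f, "try-error")) next
      eta <- cbind(1, x[!tr, , drop = FALSE]) %*%
        rbind(f$beta0_path, f$beta_path)
      mu <- expit(pmin(pmax(eta, -30), 30))
      dev[k, ] <- -2 * colSums(y[!tr] * log(mu) + (1 - y[!tr]) * log(1 - mu))
    } else {
      f <- try(fit_penalized_cox(x[tr, , drop = FALSE], time[tr], event[tr],
                                 spec, lambda = lambda), silent = TRUE)
      if (inherits(f, "try-error")) next
      # V&VH-style CV partial likelihood on the full data minus training
      ordf <- order(time)
      for (l in seq_along(lambda)) {
        eta_all <- drop(x %*% f$beta_path[, l])
        ll_all <- cox_wz(eta_all[ordf], time[ordf], as.integer(event[ordf]))$loglik
        ordt <- order(time[tr])
        eta_tr <- drop(x[tr, , drop = FALSE] %*% f$beta_path[, l])
        ll_tr <- cox_wz(eta_tr[ordt], time[tr][ordt],
                        as.integer(event[tr][ordt]))$loglik
        dev[k, l] <- -2 * (ll_all - ll_tr)
      }
    }
  }
  colMeans(dev, na.rm = TRUE)
}

#' Karush-Kuhn-Tucker residuals of a penalized fit
#'
#' Maximum stationarity violation of the penalized (partial) likelihood at
#' the fitted coefficients, per path point: for inactive coordinates the
#' excess of the absolute gradient over the penalty's subdifferential bound,
#' for active coordinates the absolute stationarity residual. Gradients are
#' on the standardized scale and the loss is scaled by 1/n, matching the
#' solver's objective (the MCP concavity is curvature-rescaled exactly as in
#' the solver).
#'
#' @param fit A `penfit`.
#' @param x,y,time,event The data the fit was produced from.
#' @param which_lambda Path indices to check (default: all converged).
#' @return Numeric vector of maximum KKT violations, one per checked path
#'   point.
#' @export
penalized_kkt <- function(fit, x, y = NULL, time = NULL, event = NULL,
                          which_lambda = NULL) {
  std <- fit$standardization
  x <- as.matrix(x)
  n <- nrow(x)
  if (fit$family == "cox") {
    ord <- order(time)
    ts <- as.numeric(time[ord]); ev <- as.integer(event[ord])
  }
  xs <- std$x
  if (is.null(which_lambda)) which_lambda <- which(fit$converged)
  pc <- .pen_code(fit$spec)
  gam <- if (is.finite(pc$gamma)) pc$gamma else 1e12
  pf <- fit$penalty_factor
  vapply(which_lambda, function(l) {
    b_std <- fit$beta_path[std$keep, l] * std$s[std$keep]
    lam <- fit$lambda[l]
    if (fit$family == "binomial") {
      eta <- fit$beta0_path[l] +
        drop(x[, std$keep, drop = FALSE] %*% fit$beta_path[std$keep, l])
      mu <- expit(pmin(pmax(eta, -30), 30))
      grad <- -drop(crossprod(xs, y - mu)) / n
      w <- pmax(mu * (1 - mu), 1e-6)
    } else {
      eta <- drop(xs %*% b_std)
      wz <- cox_wz(eta, ts, ev)
      grad <- -drop(crossprod(xs, wz$grad)) / n
      w <- pmax(wz$hess, 1e-8)
    }
    v <- drop(crossprod(xs^2, w)) / n
    viol <- numeric(length(b_std))
    for (j in seq_along(b_std)) {
      bj <- b_std[j]
      if (pc$pen == 0L) {
        if (bj == 0) {
          viol[j] <- max(0, abs(grad[j]) - lam * pc$alpha * pf[j])
        } else {
          viol[j] <- abs(grad[j] + lam * pc$alpha * pf[j] * sign(bj) +
                           lam * (1 - pc$alpha) * pf[j] * bj)
        }
      } else {
        lp <- lam * pf[j]
        if (bj == 0) {
          viol[j] <- max(0, abs(grad[j]) - lp)
        } else {
          dpen <- max(0, lp - abs(bj) * v[j] / gam) * sign(bj)
          viol[j] <- abs(grad[j] + dpen)
        }
      }
    }
    max(viol)
  }, numeric(1))
}

#' MCP penalty function
#'
#' `lambda |t| - t^2 / (2 gamma)` for `|t| <= gamma lambda`, constant
#' `gamma lambda^2 / 2` beyond.
#'
#' @param t Coefficient value(s).
#' @param lambda Penalty level.
#' @param gamma Concavity (> 1).
#' @return Penalty value(s).
#' @export
mcp_penalty <- function(t, lambda, gamma = 3) {
  at <- abs(t)
  ifelse(at <= gamma * lambda, lambda * at - t^2 / (2 * gamma),
         gamma * lambda^2 / 2)
}

#' @export
print.penfit <- function(x, ...) {
  cat("<penfit>", x$family, "/", x$spec$family,
      sprintf("(%d lambda, tuned by %s)\n", length(x$lambda), x$spec$tuning))
  cat("  selected lambda =", signif(x$lambda_selected, 4),
      " support size =", length(x$support), "\n")
  invisible(x)
}

#' Select candidate instruments by penalized logistic regression
#'
#' Runs [fit_penalized_logistic()] of the exposure on the screened
#' exposure-associated columns `I0`; the selected support is the candidate
#' instrument set `I1` (original column indices).
#'
#' @param data A `mediation_data`.
#' @param screening A [sis_screen()] result.
#' @param spec A [penalty_spec()].
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_ivs <- function(data, screening, spec = penalty_spec()) {
  cols <- screening$I0
  fit <- fit_penalized_logistic(data$covariates[, cols, drop = FALSE],
                                data$exposure, spec)
  sort(cols[fit$support])
}

#' Select candidate mediators by penalized Cox regression
#'
#' Runs [fit_penalized_cox()] of the survival outcome on the screened
#' outcome-associated columns `M0`; the selected support is the candidate
#' mediator set `M1` (original column indices).
#'
#' @inheritParams select_ivs
#' @return Integer vector of selected column indices (possibly empty).
#' @export
select_mediators <- function(data, screening, spec = penalty_spec()) {
  cols <- screening$M0
  fit <- fit_penalized_cox(data$covariates[, cols, drop = FALSE],
                           data$time, data$event, spec)
  sort(cols[fit$support])
}
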