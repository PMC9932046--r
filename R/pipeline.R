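#' Pipeline configuration
#'
#' @param penalty_iv [penalty_spec()] for the instrument (logistic) selection.
#' @param penalty_med [penalty_spec()] for the mediator (Cox) selection.
#' @param tests Which mediation tests to run: any of `"sobel"`, `"joint"`,
#'   `"boot"`.
#' @param alpha Significance level.
#' @param B Bootstrap replicates (used when `"boot"` is requested).
#' @param q Bonferroni denominator; `NULL` uses the number of candidate
#'   mediators actually tested (|M1|), or supply the full mediator dimension.
#' @param proxy Stage-2 exposure proxy: `"index"` substitutes the stage-1
#'   fitted linear predictor (the intercept is absorbed by the Cox
#'   baseline); `"probability"` substitutes the fitted probability.
#' @param seed Seed governing the bootstrap resampling.
#' @param positive_only For reporting helpers: restrict to mediators with
#'   positive indirect estimates (the convention used for methylation-style
#'   analyses); the full table is always kept in the result.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(penalty_iv = penalty_spec("mcp"),
                            penalty_med = penalty_spec("mcp"),
                            tests = c("sobel", "joint", "boot"),
                            alpha = 0.05, B = 1000, q = NULL,
                            proxy = c("index", "probability"),
                            seed = NULL, positive_only = FALSE) {
  proxy <- match.arg(proxy)
  tests <- match.arg(tests, several.ok = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  structure(list(penalty_iv = penalty_iv, penalty_med = penalty_med,
                 tests = tests, alpha = alpha, B = as.integer(B), q = q,
                 proxy = proxy, seed = seed, positive_only = positive_only),
            class = "pipeline_config")
}

.run_pipeline <- function(data, config, method) {
  stopifnot(inherits(data, "mediation_data"))
  t0 <- proc.time()[["elapsed"]]
  screen <- sis_screen(data)
  I1 <- select_ivs(data, screen, config$penalty_iv)
  M1 <- select_mediators(data, screen, config$penalty_med)

  empty_result <- function(msg) {
    structure(list(method = method, screen = screen, I1 = I1, M1 = M1,
                   I2 = integer(0), stage1 = NULL, stage2 = NULL,
                   mediator_models = NULL, tests = NULL,
                   selected = list(), message = msg, config = config,
                   provenance = .provenance(config, t0)),
              class = "ivmed_result")
  }
  if (!length(M1)) return(empty_result("no candidate mediators selected"))
  I2 <- if (method == "iv") partition_candidates(I1, M1) else
    sort(setdiff(I1, M1))

  Mmat <- data$covariates[, M1, drop = FALSE]
  if (method == "iv") {
    stage1 <- fit_exposure_model(data$covariates[, I2, drop = FALSE],
                                 data$exposure)
    proxy <- if (config$proxy == "index") stage1$instrument_index
             else stage1$fitted_prob
  } else {
    stage1 <- NULL
    proxy <- data$exposure
  }
  stage2 <- fit_outcome_model_iv(proxy, Mmat, data$time, data$event)
  med <- fit_mediator_models(data$exposure, Mmat)

  q <- if (is.null(config$q)) length(M1) else config$q
  indirect <- med$lambda_hat * stage2$gamma_hat
  tab <- data.frame(
    mediator = colnames(Mmat), column = M1,
    lambda = unname(med$lambda_hat), se_lambda = unname(med$se_lambda),
    gamma = unname(stage2$gamma_hat), se_gamma = unname(stage2$se_gamma),
    indirect = unname(indirect), row.names = NULL)
  if ("sobel" %in% config$tests) {
    tab$p_sobel <- unname(sobel_test(med$lambda_hat, med$se_lambda,
                                     stage2$gamma_hat,
                                     pmin(stage2$se_gamma, 1e6)))
    tab$p_sobel_adj <- bonferroni_adjust(tab$p_sobel, q)
  }
  if ("joint" %in% config$tests) {
    tab$p_joint <- unname(joint_test(med$p_lambda, stage2$p_gamma))
    tab$p_joint_adj <- bonferroni_adjust(tab$p_joint, q)
  }
  if ("boot" %in% config$tests) {
    bt <- bootstrap_test(data, I2, M1, B = config$B, alpha = config$alpha,
                         seed = config$seed, method = method)
    tab$boot_ci_low <- bt$ci_low
    tab$boot_ci_high <- bt$ci_high
    tab$boot_significant <- bt$significant
    tab$boot_B <- bt$boot_B
  }
  selected <- lapply(setNames(config$tests, config$tests), function(tt)
    decide_mediators(tab, config$alpha, tt))
  structure(list(method = method, screen = screen, I1 = I1, M1 = M1, I2 = I2,
                 stage1 = stage1, stage2 = stage2, mediator_models = med,
                 tests = tab, selected = selected, message = NULL,
                 config = config, provenance = .provenance(config, t0)),
            class = "ivmed_result")
}

.provenance <- function(config, t0) {
  list(seed = config$seed,
       package_version = as.character(utils::packageVersion("ivmedsurv")),
       elapsed_s = proc.time()[["elapsed"]] - t0,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the proposed IV-based mediation pipeline
#'
#' Executes the full procedure on one dataset: (1) sure-independence
#' screening of exposure- and outcome-associated columns; (2) penalized
#' logistic selection of candidate instruments; (3) penalized Cox selection
#' of candidate mediators; (4) removal of mediator columns from the
#' instrument set; (5) two-stage estimation — logistic stage-1 exposure
#' model on the instruments, Cox stage-2 outcome model on the instrumented
#' exposure index and the candidate mediators, OLS exposure-to-mediator
#' models; (6) Sobel / joint / percentile-bootstrap tests of each indirect
#' effect; (7) Bonferroni adjustment and the significance decision.
#'
#' An empty candidate-mediator set short-circuits into an empty (but valid)
#' result; an empty instrument set is an error.
#'
#' @param data A `mediation_data` (from [generate_dataset()] or
#'   [validate_input()]).
#' @param config A [pipeline_config()].
#' @return An object of class `ivmed_result`: selection sets (`I1`, `M1`,
#'   `I2`), stage fits, the per-mediator `tests` table (estimates, raw and
#'   adjusted p-values, bootstrap CI), and the per-test `selected` mediator
#'   columns.
#' @export
run_proposed <- function(data, config = pipeline_config()) {
  .run_pipeline(data, config, "iv")
}

#' Run the classical (unadjusted) comparator pipeline
#'
#' Identical to [run_proposed()] except that the stage-2 Cox model uses the
#' observed exposure instead of the instrumented index, i.e. no correction
#' for unmeasured confounding.
#'
#' @inheritParams run_proposed
#' @return An `ivmed_result`.
#' @export
run_classical <- function(data, config = pipeline_config()) {
  .run_pipeline(data, config, "classical")
}

#' @export
print.ivmed_result <- function(x, ...) {
  cat("<ivmed_result>", if (x$method == "iv") "proposed IV method"
      else "classical (unadjusted)", "\n")
  if (!is.null(x$message)) {
    cat("  ", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  screening t = %d; |I1| = %d, |M1| = %d, |I2| = %d\n",
              x$screen$t, length(x$I1), length(x$M1), length(x$I2)))
  tab <- x$tests
  if (isTRUE(x$config$positive_only)) tab <- tab[tab$indirect > 0, ]
  cat("  candidate mediators:\n")
  print(format(tab, digits = 3), row.names = FALSE)
  for (tt in names(x$selected))
    cat("  significant (", tt, "): ",
        if (length(x$selected[[tt]]))
          paste(x$selected[[tt]], collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}
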