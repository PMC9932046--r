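#' False discovery rate and positive selection rate of a selection
#'
#' `FDR = FP / (FP + TP)` with the convention `FDR = 0` when nothing is
#' selected; `PSR = TP / (TP + FN)`.
#'
#' @param selected Selected indices (any vector; duplicates ignored).
#' @param truth True indices (non-empty for PSR to be meaningful).
#' @return Named list `fdr`, `psr` (plus counts `tp`, `fp`, `fn`).
#' @export
compute_fdr_psr <- function(selected, truth) {
  selected <- unique(selected)
  truth <- unique(truth)
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  fn <- length(setdiff(truth, selected))
  fdr <- if (tp + fp == 0) 0 else fp / (fp + tp)
  psr <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  list(fdr = fdr, psr = psr, tp = tp, fp = fp, fn = fn)
}

#' Monte-Carlo mean and mean squared error of replicate estimates
#'
#' @param estimates Per-replicate estimates (NAs, e.g. replicates where the
#'   mediator was not selected, are dropped with a count).
#' @param true_value Generating value.
#' @return List with `mean`, `mse`, `n_used`, `n_dropped`.
#' @export
compute_mse <- function(estimates, true_value) {
  used <- estimates[!is.na(estimates)]
  if (length(used) < 2) stop("need at least 2 non-missing replicates")
  list(mean = mean(used), mse = mean((used - true_value)^2),
       n_used = length(used), n_dropped = sum(is.na(estimates)))
}

.derive_seeds <- function(seed, reps) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, reps)
}

#' Benchmark the penalized selectors for instrument selection
#'
#' For each selector family and each (n, censoring) design cell, generates
#' replicated scenario datasets, runs screening, penalized logistic
#' instrument selection and penalized Cox mediator selection, removes
#' mediator columns from the instrument set, and scores the resulting
#' candidate instrument set `I2` against the true instrument columns.
#'
#' @param selectors Penalty families to compare.
#' @param n,censor Vectors of sample sizes and censoring rates (the grid is
#'   their cross product).
#' @param reps Replicates per cell.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param scenario `"s1"` or `"s2"`.
#' @return A data.frame with one row per (selector, n, censor) cell: mean
#'   FDR, mean PSR, replicates used and failures.
#' @export
run_selector_benchmark <- function(selectors = c("lasso", "alasso", "enet",
                                                 "mcp"),
                                   n = 500, censor = 0.2, reps = 100,
                                   seed = 1, scenario = "s1") {
  grid <- expand.grid(n = n, censor = censor, stringsAsFactors = FALSE)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    seeds <- .derive_seeds(seed + g - 1L, reps)
    cells <- lapply(selectors, function(s)
      list(fdr = numeric(0), psr = numeric(0), fail = 0L))
    names(cells) <- selectors
    med_spec <- penalty_spec("mcp")
    for (r in seq_len(reps)) {
      cfg <- scenario_config(scenario, n = grid$n[g],
                             censor_rate_target = grid$censor[g],
                             seed = seeds[r])
      data <- generate_dataset(cfg)
      screen <- sis_screen(data)
      M1 <- try(select_mediators(data, screen, med_spec), silent = TRUE)
      for (s in selectors) {
        res <- try({
          I1 <- select_ivs(data, screen, penalty_spec(s))
          if (inherits(M1, "try-error")) stop(M1)
          I2 <- sort(setdiff(I1, M1))
          compute_fdr_psr(I2, data$truth$iv_cols)
        }, silent = TRUE)
        if (inherits(res, "try-error")) {
          cells[[s]]$fail <- cells[[s]]$fail + 1L
        } else {
          cells[[s]]$fdr <- c(cells[[s]]$fdr, res$fdr)
          cells[[s]]$psr <- c(cells[[s]]$psr, res$psr)
        }
      }
    }
    for (s in selectors) {
      out[[length(out) + 1L]] <- data.frame(
        selector = s, n = grid$n[g], censor = grid$censor[g],
        fdr = mean(cells[[s]]$fdr), psr = mean(cells[[s]]$psr),
        reps_used = length(cells[[s]]$fdr), failures = cells[[s]]$fail)
    }
  }
  do.call(rbind, out)
}

#' Benchmark mediator detection and indirect-effect estimation
#'
#' For each (method, n, censoring) design cell, generates replicated
#' scenario datasets, runs the full pipeline, and scores each requested
#' mediation test's declared mediator set against the true mediators
#' (FDR/PSR), along with the per-structured-mediator indirect-effect
#' estimates (mean and MSE against the generating `lambda * gamma`;
#' replicates where a mediator was not selected contribute no estimate).
#'
#' @param methods `"iv"`, `"classical"` or both.
#' @param tests Mediation tests to score.
#' @param n,censor Design cells (cross product).
#' @param scenario `"s1"` or `"s2"`.
#' @param reps Replicates per cell.
#' @param B Bootstrap replicates (when `"boot"` is scored).
#' @param alpha Significance level.
#' @param seed Base seed.
#' @return List with `cells` (FDR/PSR per method x test x cell) and
#'   `estimates` (per-mediator mean/MSE per method x cell).
#' @export
run_mediation_benchmark <- function(methods = c("iv", "classical"),
                                    tests = c("sobel", "joint", "boot"),
                                    n = 500, censor = 0.2, scenario = "s1",
                                    reps = 100, B = 200, alpha = 0.05,
                                    seed = 1) {
  grid <- expand.grid(n = n, censor = censor, stringsAsFactors = FALSE)
  cells <- list()
  ests <- list()
  for (g in seq_len(nrow(grid))) {
    seeds <- .derive_seeds(seed + g - 1L, reps)
    cfg0 <- scenario_config(scenario, n = grid$n[g],
                            censor_rate_target = grid$censor[g])
    n_struct <- length(cfg0$gamma_vec)
    acc <- list()
    est_acc <- list()
    for (m in methods) {
      for (tt in tests)
        acc[[paste(m, tt)]] <- list(fdr = numeric(0), psr = numeric(0))
      est_acc[[m]] <- matrix(NA_real_, reps, n_struct)
    }
    fail <- setNames(integer(length(methods)), methods)
    for (r in seq_len(reps)) {
      cfg <- scenario_config(scenario, n = grid$n[g],
                             censor_rate_target = grid$censor[g],
                             seed = seeds[r])
      data <- generate_dataset(cfg)
      truth <- data$truth
      for (m in methods) {
        res <- try({
          pc <- pipeline_config(tests = tests, alpha = alpha, B = B,
                                seed = seeds[r] %% 1000000L + r)
          if (m == "iv") run_proposed(data, pc) else run_classical(data, pc)
        }, silent = TRUE)
        if (inherits(res, "try-error")) {
          fail[m] <- fail[m] + 1L
          next
        }
        for (tt in tests) {
          sel <- res$selected[[tt]] %||% integer(0)
          sc <- compute_fdr_psr(sel, truth$mediator_cols)
          acc[[paste(m, tt)]]$fdr <- c(acc[[paste(m, tt)]]$fdr, sc$fdr)
          acc[[paste(m, tt)]]$psr <- c(acc[[paste(m, tt)]]$psr, sc$psr)
        }
        if (!is.null(res$tests)) {
          hit <- match(truth$all_structured, res$tests$column)
          est_acc[[m]][r, ] <- res$tests$indirect[hit]
        }
      }
    }
    for (m in methods) {
      for (tt in tests) {
        a <- acc[[paste(m, tt)]]
        cells[[length(cells) + 1L]] <- data.frame(
          method = m, test = tt, n = grid$n[g], censor = grid$censor[g],
          fdr = mean(a$fdr), psr = mean(a$psr), reps_used = length(a$fdr),
          failures = fail[[m]])
      }
      for (k in seq_len(n_struct)) {
        e <- est_acc[[m]][, k]
        ok <- sum(!is.na(e))
        ests[[length(ests) + 1L]] <- data.frame(
          method = m, n = grid$n[g], censor = grid$censor[g],
          mediator = k, gamma = cfg0$gamma_vec[k],
          lambda = cfg0$lambda_vec[k],
          true_indirect = cfg0$gamma_vec[k] * cfg0$lambda_vec[k],
          mean = if (ok) mean(e, na.rm = TRUE) else NA_real_,
          mse = if (ok) mean((e[!is.na(e)] -
                                cfg0$gamma_vec[k] * cfg0$lambda_vec[k])^2)
                else NA_real_,
          n_selected = ok)
      }
    }
  }
  list(cells = do.call(rbind, cells), estimates = do.call(rbind, ests))
}
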