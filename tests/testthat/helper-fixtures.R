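# Small study conditions used across tests: a reduced covariate pool keeps
# runtimes down while preserving the structure (2 IVs, 4 structured
# mediators, noise fillers, 4 withheld confounders).
small_config <- function(n = 300, p_total = 120, censor = 0.2, seed = 1, ...) {
  sim_config(n = n, p_total = p_total, censor_rate_target = censor,
             seed = seed, ...)
}

# all-structural-path-null condition: exposure and covariates carry no
# outcome signal
null_config <- function(n = 300, p_total = 160, seed = 1) {
  sim_config(n = n, p_total = p_total, beta = 0,
             gamma_vec = c(0, 0), lambda_vec = c(0, 0),
             zeta1 = rep(0, 4), zeta2 = rep(0, 4), seed = seed)
}

# small dataset plus frozen selected sets for inference-level tests
small_fitted_sets <- function(n = 200, seed = 3) {
  d <- generate_dataset(small_config(n = n, seed = seed))
  list(data = d, I2 = d$truth$iv_cols,
       M1 = sort(d$truth$all_structured))
}
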