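# ivmedsurv

High-dimensional mediation analysis for survival outcomes with unmeasured
confounders, using instrumental variables.

## What problem this solves

In observational studies — the motivating case is DNA methylation between
smoking and lung-cancer survival — researchers want to know which of
thousands of candidate molecular mediators transmit an exposure's effect
onto a censored time-to-event outcome, and how large each indirect effect
is. Standard high-dimensional mediation pipelines assume all confounders of
the exposure–outcome relation are measured; in practice they rarely are.
`ivmedsurv` addresses this with a two-stage instrumental-variable design
that needs *no* measurements of the confounders.

The structural model: with binary exposure $X$, instruments $Z$, mediators
$M$, unmeasured confounders $L$ and survival outcome,

$$h(t) = h_0(t)\exp(a + \beta X + \gamma^\top M + \zeta_1^\top L), \qquad
  M_i = c + \lambda_i X + \varepsilon_i, \qquad
  \operatorname{logit} P(X{=}1) = d + \eta^\top Z + \zeta_2^\top L.$$

The mediation effect of $M_i$ is $\lambda_i\gamma_i$. Because instruments
are independent of $L$, replacing $X$ in the hazard model by the stage-1
fitted index $\hat d + \hat\eta^\top Z$ yields an exposure proxy free of
unmeasured confounding.

The pipeline: sure-independence screening (top $\lfloor 2n/\log n \rfloor$
columns per outcome), MCP-penalized logistic regression to select candidate
instruments and MCP-penalized Cox regression to select candidate mediators
(LASSO / adaptive LASSO / elastic net are provided for comparison),
two-stage estimation of $(\eta, \beta, \gamma, \lambda)$, and per-mediator
significance testing by the Sobel test, the joint-significance test, and a
percentile bootstrap, with Bonferroni adjustment. A simulator with withheld
confounders and FDR/PSR/MSE benchmark utilities reproduce the method's
operating characteristics end to end.

The penalized solvers (coordinate descent over an IRLS working model, warm
starts, BIC or cross-validated tuning, KKT-checkable solutions) are
implemented in compiled code inside the package.

## Worked example

```r
library(ivmedsurv)

# scenario "s1": 1,000-column pool, two true mediators with
# indirect effects 1.2 x 0.8 = 0.96 and 0.8 x 1.2 = 0.96
d <- generate_dataset(scenario_config("s1", n = 500,
                                      censor_rate_target = 0.2, seed = 42))
res <- run_proposed(d, pipeline_config(tests = c("sobel", "joint"), seed = 1))
res
```

```
<ivmed_result> proposed IV method
  screening t = 160; |I1| = 6, |M1| = 6, |I2| = 3
  candidate mediators:
 mediator column  lambda se_lambda  gamma se_gamma indirect  p_sobel
    V0247    247 -0.0681    0.0930 -0.199   0.0521   0.0136 4.72e-01
    V0314    314  0.8432    0.0944  0.961   0.0589   0.8101 4.66e-15
    V0521    521  1.3268    0.0919  0.702   0.0505   0.9317 0.00e+00
    V0665    665  0.0989    0.0914  1.153   0.0685   0.1140 2.80e-01
    V0938    938 -0.2063    0.0877 -0.148   0.0497   0.0306 6.48e-02
    V0971    971  1.4476    0.0911  0.264   0.0456   0.3818 5.40e-08
 p_sobel_adj  p_joint p_joint_adj
    1.00e+00 4.64e-01    1.00e+00
    2.80e-14 4.27e-19    2.56e-18
    0.00e+00 5.80e-44    3.48e-43
    1.00e+00 2.79e-01    1.00e+00
    3.89e-01 1.87e-02    1.12e-01
    3.24e-07 7.17e-09    4.30e-08
  significant (sobel): 314, 521, 971
  significant (joint): 314, 521, 971
```

Reading this output: the true mediators (columns 314 and 521; the truth is
in `d$truth`) are detected with indirect-effect estimates 0.81 and 0.93
for a generating value of 0.96 — the expected non-collapsibility
attenuation of Cox coefficients under omitted covariates, discussed in the
methods vignette. Column 971 is the structured "exposure-child" column
(`lambda = 1.5, gamma = 0`), whose estimated product 0.38 reflects the
residual exposure signal it proxies; columns 247/938/665 are correctly not
declared. `run_classical()` runs the same pipeline with the observed
exposure (no IV correction) for comparison.

User data enter through `validate_input()` (a data frame with time, 0/1
event, 0/1 exposure and a numeric covariate block) or the CLI at
`inst/cli/ivmedsurv.R` (`simulate` / `fit` / `benchmark` subcommands).

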