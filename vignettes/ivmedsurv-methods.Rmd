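---
title: "High-dimensional mediation analysis for survival outcomes with instrumental variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-dimensional mediation analysis for survival outcomes with instrumental variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observational epigenetic studies often ask how much of an exposure's effect
on survival is transmitted through high-dimensional molecular intermediates
— for example, how much of smoking's effect on lung-cancer survival runs
through DNA-methylation changes. Three features make this hard at once:

1. the mediator pool is ultrahigh-dimensional (thousands of CpG sites,
   more than the sample size),
2. the outcome is censored time-to-event data, and
3. common causes of exposure and survival are typically unmeasured, so
   propensity-score-style adjustment is unavailable.

`ivmedsurv` implements a two-stage instrumental-variable (IV) procedure for
this setting. The structural model is

- hazard: $h(t) = h_0(t)\,\exp(a + \beta X + \gamma^\top M + \zeta_1^\top L)$,
- mediators: $M_i = c + \lambda_i X + \varepsilon_i$,
- exposure: $\mathrm{logit}\,P(X = 1) = d + \eta^\top Z + \zeta_2^\top L$,

where $X$ is a binary exposure, $M$ the mediator vector, $Z$ instruments,
and $L$ *unmeasured* confounders. The per-mediator indirect (mediation)
effect is the product $\lambda_i \gamma_i$; mediator $i$ is a true mediator
iff $\lambda_i \gamma_i \neq 0$. Because $Z \perp L$, substituting the
fitted exposure index $\hat d + \hat\eta^\top Z$ for $X$ in the hazard
model removes the dependence of the exposure proxy on $L$.

## The pipeline

`run_proposed()` executes, in order:

1. **Screening.** Sure-independence screening reduces the covariate pool to
   the top $t = \lfloor 2n/\log n\rfloor$ columns by marginal association
   with the exposure (set $I_0$, logistic score $z$) and with the outcome
   (set $M_0$, Cox partial-likelihood score $z$). We use score statistics
   because both are available in closed form under the null and vectorise
   over all columns in $O(np)$; they are asymptotically equivalent to the
   corresponding Wald statistics. The natural logarithm and the floor
   convention define $t$.
2. **Instrument selection.** MCP-penalized logistic regression of $X$ on
   the $I_0$ columns; the selected support is $I_1$.
3. **Mediator selection.** MCP-penalized Cox regression of the outcome on
   the $M_0$ columns; the selected support is $M_1$.
4. **Partition.** $I_2 = I_1 \setminus M_1$ are the candidate instruments;
   everything in $M_1$ is a candidate mediator. An empty $I_2$ is an error
   ("no valid instruments"); an empty $M_1$ short-circuits to an empty
   result.
5. **Two-stage estimation.** Stage 1: unpenalized logistic MLE of $X$ on
   the $I_2$ columns; the fitted linear predictor is the instrument index.
   Stage 2: unpenalized Cox MLE (Efron ties) of the outcome on the index
   plus the $M_1$ columns gives $\hat\beta$ and $\hat\gamma_i$ with Wald
   SEs. $\hat\lambda_i$ comes from per-mediator OLS of $M_i$ on the
   *observed* $X$, exactly as the mediator model is stated.
6. **Testing.** Per mediator: the Sobel test
   $p = 2\{1 - \Phi(|\hat\lambda\hat\gamma|/\hat s)\}$ with
   $\hat s = \sqrt{\hat\lambda^2 S_\gamma^2 + \hat\gamma^2 S_\lambda^2}$;
   the joint-significance test $p = \max(p_\lambda, p_\gamma)$; and a
   percentile bootstrap of $\hat\lambda_i\hat\gamma_i$ (resampling rows,
   re-estimating stage 1/2 and the OLS slopes on the *frozen* selected
   sets; significance = the $1-\alpha$ interval excludes 0).
7. **Multiplicity.** Bonferroni: $p_{\mathrm{adj}} = \min(p \cdot q, 1)$,
   by default with $q = |M_1|$ (the tests actually performed; the full
   mediator dimension can be supplied instead). Adjusted $p < \alpha$
   declares a mediator.

`run_classical()` is the same pipeline with the observed exposure in place
of the instrument index in stage 2 — the "unadjusted" comparator.

## The penalized solvers

MCP-penalized logistic and Cox solvers are implemented in compiled
coordinate descent (IRLS outer loops on the likelihood or Efron partial
likelihood, weighted coordinate descent inner loops, warm starts along a
100-point log-spaced path from the data-derived $\lambda_{\max}$ down to
$0.01\,\lambda_{\max}$ for logistic and $0.05\,\lambda_{\max}$ for Cox
fits). LASSO, adaptive LASSO (weights $1/|\hat\beta|$ from a small-ridge
initial fit, stabilising the initialisation when $p \approx n$) and
elastic net share the same engine, which is how the selector comparison
benchmark treats all four families identically.

Numerical choices worth knowing:

- Columns are standardized internally (population SD); coefficients are
  reported on the original scale, making the selected support invariant to
  column scaling.
- The MCP concavity is rescaled per coordinate by the IRLS curvature
  ($\gamma_j = \gamma / v_j$), which keeps every one-dimensional update
  strictly convex for any weights; with unit curvature this is the plain
  MCP, and as $\gamma \to \infty$ the solution path converges to the
  LASSO path (tested to $10^{-4}$ at $\gamma = 10^6$).
- Stationarity (KKT) residuals of the penalized objective are checkable
  per path point via `penalized_kkt()` and are kept below $10^{-6}$.
- In the complete-separation / monotone-likelihood region at small
  $\lambda$ the path is truncated and the remaining points flagged
  unconverged; tuning only considers converged fits.
- Tuning is by BIC ($-2\ell + \mathrm{df}\log n$) over the path by
  default; 10-fold cross-validated deviance is available (`tuning =
  "cv10"`). The selection literature offers sparser criteria for
  $p \approx n$, but BIC is the package default and both options are
  exposed.
- Ties in the Cox partial likelihood use the Efron approximation, matching
  `survival::coxph`.

## The simulator

`generate_dataset()` reproduces the benchmark study conditions: two
independent normal instruments (SDs 0.9 and 1.1), four withheld
confounders (normals with SDs 0.8 and 1.2, Bernoullis with rates 0.4 and
0.6), a binary exposure drawn from the logistic model with
$\zeta_2 = (0.4, 0.5, 0.6, 0.7)$, normally distributed mediators with unit
noise SD, and survival times drawn by inverse transform from an
exponential-baseline ($h_0 = 1$) Cox hazard with $\beta = 1.5$ and
$\zeta_1 = (0.4, 0.5, 0.6, 0.7)$. Censoring is independent exponential
with its rate solved by `calibrate_censoring()` (root-finding on the
realized linear predictors) so the expected censoring fraction equals the
20/40/60% design value; with homogeneous linear predictors the solution
reduces to the closed form $\theta = r\,\mathrm{target}/(1 -
\mathrm{target})$, which is the unit-test oracle. Scenario `"s1"` has
1,000 total covariates with $\gamma = (1.2, 0.8, 1.5, 0, \ldots)$ and
$\lambda = (0.8, 1.2, 0, 1.5, 0, \ldots)$ (two true mediators, indirect
effects 0.96); scenario `"s2"` has 3,000 covariates and four true
mediators ($\pm 0.96$). Values the benchmark design leaves open were fixed
once: $\eta = (1.0, 1.5)$ (strong instruments, first-stage marginal
$z > 5$ at $n = 500$), intercepts 0, mediator noise SD 1. Observed columns
are shuffled so position carries no information; the true indices travel
in the `truth` field. Noise fillers are iid $N(0,1)$, which coincides with
the null-mediator model $M_i = 0\cdot X + \varepsilon$.

The generator deliberately honours the mediator-independence and
no-mediator-outcome-confounding assumptions (A2/A3): mediators carry no
loading on $L$ and are conditionally independent given $X$. An optional
log-normal frailty in the hazard (`frailty_sd`) is off by default — with
it on, the outcome model would no longer be the proportional-hazards model
the estimator fits, so it exists only for sensitivity runs.

## What the benchmarks can and cannot show

Two structural facts about this DGP shape the results and are worth
stating plainly, because they bound what *any* implementation of the
procedure can achieve on it:

**Non-collapsibility.** Cox coefficients attenuate when independent risk
factors are omitted. Both stage-2 fits omit $\zeta_1^\top L$
(variance $\approx 0.67$), so $\hat\gamma$ is attenuated by roughly
$1/\sqrt{1 + \mathrm{var}(\zeta_1^\top L)} \approx 0.77$ in either arm —
we measure $\hat\gamma_1 \approx 0.92$–$0.93$ (truth 1.2) at
$n = 20{,}000$ with selection bypassed. The instrument index removes the
*confounding* of the exposure but cannot restore collapsibility, so
indirect-effect products are recovered with a systematic attenuation
factor, not exactly. Detection (are $\lambda_i$ and $\gamma_i$ nonzero?)
is unaffected, which is why the PSR benchmarks sit near 1 while the mean
recovered product sits below $\lambda\gamma$.

**Exposure-child mediators mimic instruments.** A column with
$\lambda_i \neq 0$ but $\gamma_i = 0$ (scenario 1's fourth structured
mediator) is exposure-associated, outcome-independent given $X$, and
confounder-independent — statistically indistinguishable from a valid
instrument. Whether it lands in $I_2$ depends on whether the penalized Cox
step happens to co-select it, so instrument-selection FDR against the
nominal two-instrument truth has an irreducible component, and at larger
$n$ the Cox step increasingly absorbs the true instruments themselves
(they carry outcome signal through $X$), occasionally emptying $I_2$ — the
documented "no valid instruments" error, which the benchmark utilities
count and exclude. Under the generating model such a column *is* a valid
instrument, so downstream estimates are not harmed; only the selection
bookkeeping is.

The classical comparator deserves one more caveat: with mediators
generated free of confounder loadings (assumption A3), the
mediator–outcome path is unconfounded *given the observed exposure*, so
the classical arm's indirect estimates are attenuated in the same way as
the IV arm's rather than inflated; unmeasured confounding shows up in its
direct-effect coefficient instead. Benchmarks on data violating A3 — where
a classical analysis genuinely inflates — are outside what this generator
emulates.

Real methylation data differ from the generator in further ways the
benchmarks cannot speak to: beta-values are bounded and skewed (the
simulator's mediators are Gaussian), mediators are correlated in blocks
(A2 is enforced in generation), and instrument validity is assumed rather
than guaranteed.

## Problem sizes and reproducibility

The shipped benchmarks use 50–100 replicates per design cell with
$B = 200$ bootstrap replicates, the scale at which the full grid runs on a
single core in minutes; all replicate streams are derived from one base
seed, and `generate_dataset()`, `run_proposed()` and `bootstrap_test()`
are bit-reproducible given seeds. `scripts/acceptance.R` regenerates every
headline quantity from scratch.

## Worked example

```{r example, eval = FALSE}
library(ivmedsurv)

d <- generate_dataset(scenario_config("s1", n = 500,
                                      censor_rate_target = 0.2, seed = 42))
res <- run_proposed(d, pipeline_config(tests = c("sobel", "joint"),
                                       seed = 1))
res
res$selected$sobel          # declared mediator columns
d$truth$mediator_cols       # generating truth
```

For user data, read a CSV with `validate_input()` (columns: survival time,
0/1 event indicator, 0/1 exposure, then the covariate pool) and pass the
result to `run_proposed()`. A thin command-line front end with
`simulate` / `fit` / `benchmark` subcommands ships in
`inst/cli/ivmedsurv.R`.

## Known limitations

- Binary exposures only; no ordinal or continuous exposure support.
- Mediator correlation is neither modelled nor exploited (A2).
- Stage-2 Wald SEs are naive with respect to stage-1 uncertainty; the
  percentile bootstrap is the recommended inference for intervals.
- The bootstrap freezes the selected sets; selection uncertainty is not
  propagated.
- Indirect-effect products inherit the non-collapsibility attenuation
  discussed above; comparisons across models with different covariate sets
  should be interpreted accordingly.
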