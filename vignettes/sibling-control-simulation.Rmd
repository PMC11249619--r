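---
title: "Measurement error and false familial confounding in sibling control designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error and false familial confounding in sibling control designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sibling and co-twin control designs compare exposure–outcome associations
*within* families to rule out confounders shared by siblings. The standard
analysis regresses the outcome on the individual's exposure plus the
family-mean exposure: a non-zero family-mean coefficient is conventionally
read as evidence of familial confounding, and attenuation of the individual
exposure coefficient relative to an uncontrolled model is read the same way.

Classical measurement error in the exposure breaks this logic. Differencing
siblings removes shared *true-score* variance but none of the error
variance, so the within-family signal-to-noise ratio is worse than the
population one. A truly causal effect therefore looks attenuated within
families, and the deficit loads onto the family-mean coefficient — exactly
the signature of confounding, produced with none present. `sibcontrol`
simulates this situation and quantifies two things: the attenuation of the
causal estimate, and the probability of obtaining a small family-mean
p-value (the risk of falsely concluding familial confounding).

## The generating model

Each family contributes $k$ siblings (default 2). On standardized latent
scales:

* True exposures $T_1, \dots, T_k$ are standard normal with exchangeable
  within-family correlation $\rho_T = \rho_{obs} / \lambda$, where
  $\rho_{obs}$ is the *observed* sibling correlation of the measured
  exposure and $\lambda$ is the reliability of the measure. Parameterizing
  by $\rho_{obs}$ keeps conditions comparable to what a practitioner sees
  in data; $\rho_{obs} > \lambda$ would imply $\rho_T > 1$ and is rejected
  as impossible.
* Observed exposures add independent error,
  $X_i = T_i + e_i$, $e_i \sim N(0, (1-\lambda)/\lambda)$, so
  $\mathrm{var}(X) = 1/\lambda$ and the true score accounts for exactly
  $\lambda$ of the observed variance. $X$ is deliberately *not*
  re-standardized after error injection; slopes are per unit of observed
  exposure, which is what an analyst of real data estimates.
* The latent outcome is $Y^*_i = b\,T_i + u_f + u_i$ with
  $\mathrm{var}(u_f) = s(1-b^2)$ shared within family and
  $\mathrm{var}(u_i) = (1-s)(1-b^2)$ individual, giving
  $\mathrm{var}(Y^*) = 1$. There is no confounding path of any kind: the
  family-mean exposure's true coefficient is zero. The shared residual
  fraction defaults to $s = 0$ — outcome clustering then arises only
  through the correlated true exposures. This default matters because the
  single-item analysis uses an ordered probit with no clustering
  correction, which is well calibrated only when residual clustering is
  small; $s$ is exposed as a parameter for sensitivity analyses.

Two outcome types are generated:

* **Single item** (`single_item`): $Y^*$ is cut at fixed thresholds into
  codes 1–5. Thresholds are exact standard-normal quantiles of the
  cumulative target category proportions, so the generated margins match
  the targets by construction rather than using round cutpoints. Shipped
  margins: symmetric (3.6, 23.8, 45.2, 23.8, 3.6)%, moderately asymmetric
  (75.2, 9.1, 6.8, 5.1, 3.8)%, and highly asymmetric (90, 4, 3, 2, 1)%.
  The single item is a direct categorization of $Y^*$, with no
  item-specific noise.
* **Aggregate** (`aggregate5`): five item latents
  $L_j = 0.7\,Y^* + \sqrt{1-0.7^2}\,\nu_j$ (so the outcome factor explains
  49% of each item latent's variance), each categorized at the same
  thresholds; the outcome is the mean of the five codes, treated downstream
  as if continuous — the common mean-score practice for questionnaire
  scales.

## The analysis models

* Single-item outcomes: maximum-likelihood **ordered probit**
  (`MASS::polr`), uncontrolled ($X$ only) and sibling control ($X$ plus
  family mean $M$), no family-clustering adjustment — deliberately
  mirroring common practice, not endorsing it. Because the probit fixes
  the latent residual variance at 1, adding predictors inflates the
  implied total latent variance and re-scales coefficients; all regression
  coefficients are therefore also reported standardized by
  $\sqrt{\hat v + 1}$ with $\hat v$ the sample variance of the fitted
  linear predictor (regression terms only). This makes the uncontrolled
  and controlled coefficients comparable on the latent-outcome-SD scale;
  p-values are unaffected.
* Aggregate outcomes: **random-intercept linear mixed model**
  (`lme4::lmer`), REML, refit by plain maximum likelihood when the
  random-intercept variance lands on the zero boundary (with $s = 0$ and
  predictors controlled, the truth is essentially on that boundary, so a
  singular fit is flagged, not treated as failure).
* p-values are two-sided Wald with the standard-normal reference for both
  model families. lme4 reports no p-values natively; with 500–5000
  families the normal reference is accurate and keeps the two families
  consistent. Non-converged fits are retried once from perturbed starting
  values, then kept with `converged = FALSE` and excluded (and counted) by
  all summaries; a condition with more than 1% failures aborts loudly.

## Closed-form references

For a *continuous* outcome the population slopes have closed forms, used
as independent oracles in the tests and available via `expected_slopes()`:
uncontrolled $b\lambda$; within (sibling-control exposure)
$b(\lambda-\rho_{obs})/(1-\rho_{obs})$; family mean
$2b\rho_{obs}(1-\lambda)/(1-\rho_{obs}^2)$. At $\lambda = 1$ these reduce
to $(b, b, 0)$; at $\rho_{obs} = \lambda$ the within slope is exactly zero
— siblings' true exposures are identical and the design carries no causal
information. For ordinal outcomes the oracles are qualitative references
only: categorization introduces additional mild attenuation (the 5-category
symmetric code retains about 89% of the latent variance, the 5-item mean
score about 80%).

## Reproducibility and numerical choices

* One master seed governs everything. Each grid cell receives a sub-seed
  derived by fixed integer mixing over $2^{31}-1$, and each replicate
  derives its own sub-seed from the cell seed, so any (condition,
  replicate) pair is bit-identical regardless of execution order, and
  grids can be re-run or extended without disturbing existing cells.
* Thresholds reject non-positive category proportions (a quantile at 0 or
  1 is infinite) and proportions that do not sum to 1 within $10^{-6}$.
* Risk uses the weak inequality $p \le \alpha$; the default threshold grid
  is $\{0.05, 0.01, 0.001\}$; every proportion is accompanied by its
  binomial Monte Carlo standard error.
* `run_grid()` separates the expensive simulate-and-fit stage from
  summarizing: risks at new thresholds, power, estimate means, and
  p-value ECDFs are all recomputed from the stored tidy table.

## Problem sizes

The reference simulations in the package's tests and in
`scripts/acceptance.R` use the main study scale — 2000 sibling pairs, true
effect $b = 0.3$, symmetric outcomes — with 300–400 Monte Carlo replicates
per condition, giving binomial standard errors below 2.5 percentage points
on risk proportions; monotonicity checks use 100 replicates at the
sample-size extremes (500 and 5000 pairs), where the effects being ordered
are many standard errors apart. The closed-form oracle comparisons use a
single replicate of $10^5$ pairs with the continuous latent outcome.

## A worked example

```{r example}
library(sibcontrol)

conds <- condition_grid(
  n_pairs = 2000, n_reps = 500, beta = 0.3,
  rho_obs = c(0.2, 0.4, 0.6), reliability = c(1, 0.9, 0.8, 0.7, 0.6)
)
grid <- run_grid(conds)

summarize_estimates(grid)   # attenuation of the causal estimate
confounding_risk(grid)      # risk of a false confounding conclusion
causal_power(grid)          # power for the attenuated within effect
plot_estimates(grid)
plot_pvalue_ecdf(grid)
```

## What the simulation does and does not emulate

The generator reproduces the mechanisms that drive the phenomenon:
correlated true exposures, independent classical measurement error,
latent-threshold ordinal responses, and mean-score aggregation. Passing
tests therefore show that the *estimators behave as the theory of
classical measurement error predicts under this generating model*. They do
not show that real sibling data are this clean: the model has no
confounding (by construction), no non-shared confounders, no mediators, no
carry-over between siblings, no selection into the sample, no
differential or correlated measurement error, and no reliability
differences between siblings. A real study exhibiting the simulated
signature could still involve genuine confounding; conversely these
results show the signature alone cannot establish it.

Known limitations: binary outcomes and logistic models are out of scope;
the ordered probit deliberately ignores residual within-family clustering
(with a large shared outcome residual fraction its family-mean p-values
become anti-conservative — use the aggregate/linear path or keep $s$
small); and the closed-form slopes apply to continuous outcomes only, so
ordinal-outcome comparisons against them use simulation-based tolerances.

One empirical regularity worth flagging: at the same reliability and
sibling correlation, the family-mean test applied to the 5-item mean score
(linear mixed model) is noticeably *less* often significant at strict
thresholds than the single-item probit test, because the mean score
retains only ~80% of the latent outcome variance while the probit operates
on a direct categorization retaining ~89%. Comparisons of the two outcome
types should account for this measurement gap in the outcome itself.
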