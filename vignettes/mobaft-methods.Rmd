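---
title: "Model-based recursive partitioning with parametric AFT models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based recursive partitioning with parametric AFT models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobaft)
library(survival)
```

## The model

All survival models in this package are log-location-scale accelerated
failure time (AFT) models for a right-censored time-to-event outcome:

$$\log T = x'\beta + \sigma\,\varepsilon,$$

where $x$ is a covariate vector with intercept, $\beta$ acts multiplicatively
on the time scale (a coefficient $\beta_j$ means a one-unit increase in $x_j$
multiplies survival time by $e^{\beta_j}$ — the *time ratio* or acceleration
factor), $\sigma > 0$ is a scale parameter, and the law of the standardized
residual $\varepsilon$ picks the family:

| family        | residual law                    | scale          |
|---------------|---------------------------------|----------------|
| exponential   | standard minimum extreme value  | fixed, $\sigma \equiv 1$ |
| Weibull       | standard minimum extreme value  | free           |
| log-logistic  | standard logistic               | free           |
| lognormal     | standard normal                 | free           |

The exponential family is exactly the Weibull with the scale pinned at 1, so
the two are likelihood-nested with one degree of freedom between them.

With right censoring (event indicator $\delta_i$), the log-likelihood is
$\sum_{\delta_i = 1}\log f(t_i) + \sum_{\delta_i = 0}\log S(t_i)$. The
numerical optimisation over $(\beta, \log\sigma)$ is delegated to
`survival::survreg()`, the standard censored-ML engine for exactly this
parameterisation; the package evaluates its own analytic log-likelihood
(`aft_loglik()`) and per-subject score contributions (`aft_scores()`) at the
reported optimum and sets the `converged` flag from the gradient max-norm
(tolerance $10^{-4} n$), rather than trusting the optimiser's status.
Standard errors come from the observed-information inverse. Predicted median
survival is $\exp(x'\beta)\,m(\sigma)$ with $m(\sigma) = (\log 2)^\sigma$ for
the extreme-value families and $1$ for the symmetric-residual families.

Times must be strictly positive (log-time is undefined at zero); zero or
negative times are rejected rather than floored, and a dataset with no
events is refused because the censored likelihood is then degenerate.

## The tree

`aft_mob()` grows a *model-based* recursive partition: every node carries a
full AFT model over the **model covariates** (default `er + age`), and the
tree splits over the **partitioning covariates** (default
`her2 + pr + age + er`; the two sets may overlap). One growth step is:

1. Fit the node model to the node's subjects.
2. Test the stability of the fitted parameters along each partitioning
   covariate; pick the covariate with the most significant instability. If
   none is significant at `alpha`, the node is terminal.
3. Find that covariate's split point by maximizing the summed
   log-likelihood of the two refitted children — the likelihood-based
   objective evaluated over the tree's terminal nodes.
4. Recurse on both children.

Variable selection (step 2) and cutpoint selection (step 3) deliberately use
different criteria. Testing once per covariate and only then scanning
cutpoints avoids the multiple-testing selection bias of exhaustive-search
survival trees, which examine every allowable split on every covariate.

### The instability test

The test statistic is built from the per-subject maximum-likelihood score
contributions $s_i = \partial \log L_i / \partial\theta$ at the node's fit
(columns: the $\beta$'s and $\log\sigma$ when free). If the node model is
correct and stable, the $s_i$ are mean-zero with no systematic drift along
any covariate. For an ordered covariate the subjects are sorted by it and
the statistic is the supLM functional of the cumulative score process,

$$\max_{j}\; \frac{\|W(j)\|^2}{(j/n)(1 - j/n)},\qquad
W(j) = \hat I^{-1/2} n^{-1/2} \sum_{i \le j} s_{(i)},\qquad
\hat I = \tfrac1n \sum_i s_i s_i',$$

with the maximum over the trimmed range (default `trim = 0.1` at each end)
and evaluated at the ends of tied blocks. For a categorical covariate the
statistic sums per-level Lagrange-multiplier components
$\sum_c n_c^{-1} S_c' \hat I^{-1} S_c$, $S_c = \sum_{i \in c} s_i$. Binary
0/1 markers are handled as categorical (their split is then forced); age is
ordered numeric.

P-values are obtained by within-node permutation of the covariate against
the fixed score rows, `p = (1 + #{permuted >= observed}) / (n_perm + 1)`,
with `n_perm = 999` by default. Permutation was preferred over the
asymptotic Brownian-bridge/chi-square references because it is exact at any
node size under exchangeability, costs little (the scores are fixed; a
permutation is a row shuffle), and gives the test its stated level by
construction; an asymptotic chi-square reference is reported alongside for
categorical covariates. A consequence worth knowing: the smallest attainable
p-value is $1/(n_\mathrm{perm}+1)$, so `n_perm` bounds how small adjusted
p-values can get. Across the covariates tested at a node, p-values are
Bonferroni-adjusted by default — standard conservative practice for
tree-variable selection.

Exact ties in the adjusted p-values (common when several covariates hit the
permutation floor) are broken by the declared order of the partitioning
covariates, which is therefore part of the tree's specification.

### Stopping, degrees of freedom, comparison

Growth stops when no instability is significant, when a node is too small
(`min_node_size`, default ten subjects per free node parameter) or too
event-poor (`min_events = 5` — a floor the censored likelihood needs), at
`max_depth`, or when no admissible cutpoint leaves both children above the
floors. There is no pruning.

A fitted tree's log-likelihood is the sum over terminal nodes, and its
degrees of freedom count every terminal node's free parameters plus one per
split: a two-terminal Weibull tree with two model covariates per node has
$2 \times 4 + 1 = 9$ parameters. `AIC = -2\,\ell + 2\,\mathrm{df}` then makes
trees and global models comparable, and `lrt()` treats the tree as a
high-interaction model in which the same-family global model is nested, with
df equal to the parameter-count gap. These tree LRT p-values are labelled
*nominal*: the chi-square reference ignores that the tree structure was
selected on the same data. Per-terminal-node Wald stars in printed trees are
likewise unadjusted for selection, and say so.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` produces
right-censored cohorts whose defaults emulate a hormone-receptor
breast-cancer registry cohort: $n = 1465$; age from a truncated normal
$N(54, 11.7)$ on $[20, 90]$, recorded in whole years as registries do
(median $\approx 54$, $\approx 10\%$ under 39, minimum 20); marker
positivity ER 75.8%, PR 72.5%, HER2 19%, independent by default with an
optional Gaussian-copula correlation; and exponential censoring whose rate
is solved numerically so the expected censored fraction, given the realized
event times, is 86%. The censoring mechanism is a free design choice — only
the censored *fraction* is a stated property of the emulated cohort — and
an administrative follow-up cap is available as an alternative.

Event times are drawn exactly by inverse-CDF on the standardized residual of
each subject's segment law. The *truth structure* (`cohort_truth()`) maps
mutually exclusive covariate rules to AFT laws; a single default segment
gives a homogeneous cohort, several segments encode a latent tree.
`homogeneous_truth()` uses covariate effects of $-0.02$ (age), $+0.20$ (ER),
$+0.10$ (PR), $-0.49$ (HER2) on the log-time scale with an intercept of
4.40, calibrated once so that the observed-time mean ($\approx 4.2$ yr),
median ($\approx 2.9$ yr) and 5-year Kaplan–Meier survival ($\approx 84\%$)
sit near the emulated cohort's descriptive statistics; an exponential-shaped
observed-time law cannot match such a mean and median exactly at the same
time, so the intercept is a compromise between them.
`subgroup_truth()` encodes a three-split structure — HER2+ short survival;
then PR− vs PR+ among HER2−; then age at 39 among HER2−/PR+, with a
high-burden young subgroup — with contrasts of 1–3 log-units, the package's
test-bed for partition recovery.

What the generator does *not* emulate: the real joint distribution of age
and markers beyond the printed marginals, competing risks, left truncation,
covariate measurement error, or informative censoring. Tests that pass on
these cohorts demonstrate that the machinery is correct under its own
assumptions, not that any particular clinical finding generalises.

## Numerical choices and edge cases

* Optimisation is over $(\beta, \log\sigma)$, so $\sigma > 0$ is free.
* The information matrix $\hat I$ is inverted by Cholesky with an SVD
  pseudo-inverse fallback for near-singular score covariance.
* Split-scan candidates are midpoints of consecutive distinct values;
  likelihood ties between cutpoints keep the smaller cutpoint. Candidate
  splits whose children would fall below the size/event floors are skipped.
* A node whose model does not converge becomes terminal with a warning —
  never silently dropped or silently split.
* Determinism: a cohort is a pure function of its `cohort_spec` (seed
  included), and tree growth of its `(data, mob_control)`; permutation
  draws are seeded per `mob_control$seed`, separately from cohort seeds, so
  changing `n_perm` never perturbs a cohort.
* Serialized trees (`mob_to_json()`) store numbers at 17 significant
  digits, so reloaded trees predict identically to the originals.

## Problem sizes used by the test suite

The simulation-based checks run at sizes chosen to balance statistical
resolution against a desk-scale runtime: parameter recovery at $n = 2000$
with 100 replicates per family; split-test level at $n = 150$ over 500
replicates and power at $n = 800$ over 100 replicates, both with
`n_perm = 199`; structure recovery at $n = 1500$ over 100 replicates; and
50 small instances for the split-search oracle. The full suite runs in a
few minutes on one CPU.

## Known limitations

* Only right censoring; no interval censoring, competing risks, frailty,
  time-dependent covariates, or Cox models.
* Binary splits only; no surrogate splits or missing-data handling.
* Tree inference is post-selection and reported as nominal; no honest
  sample-splitting or cross-validated model selection is provided.
* The permutation test assumes within-node exchangeability of the score
  rows under the null; covariates that modulate the score *variance*
  without shifting parameters can inflate apparent instability.
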