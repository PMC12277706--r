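---
title: "Differentially private case-control analysis: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentially private case-control analysis: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcc)
library(dplyr)
```

## The problem

Secure data environments increasingly require that statistical outputs —
not just microdata — be disclosure-controlled. Differential privacy (DP)
gives a quantifiable guarantee: a randomized release mechanism `M` is
epsilon-DP if for any two datasets `D1`, `D2` differing in one record and any
output set `S`,

$$P[M(D_1) \in S] \le e^{\varepsilon} \, P[M(D_2) \in S].$$

Smaller epsilon means more noise and stronger privacy. `dpcc` implements a
DP-enabled case-control pipeline — epsilon-DP logistic regression, propensity
score matching, and an evaluation framework that sweeps epsilon across
predetermined seeds — together with a synthetic cohort generator emulating a
published asthma-exacerbation case-control cohort (2714 cases, 19 451
controls), so the whole pipeline is reproducible without access-controlled
data.

## The private estimator: objective perturbation

The centerpiece is `dp_logistic_regression()`, an epsilon-DP regularized
logistic regression by objective perturbation. With outcome `y_i` in
{-1, +1} and feature rows `x_i` (a constant intercept entry included), the
released coefficients minimize

$$J(\beta) \;=\; \frac{1}{n}\sum_i \log\!\left(1 + e^{-y_i x_i^\top \beta}\right)
\;+\; \frac{\lambda + \Delta}{2}\,\lVert\beta\rVert^2
\;+\; \frac{b^\top \beta}{n},$$

where the noise vector `b` has direction uniform on the unit sphere and norm
drawn from `Gamma(d, 2R / eps_eff)`; `d` is the number of coefficients and
`R` the assumed bound on the feature-row L2 norm (`data_norm`). Strong
convexity of the ridge term makes the minimizer a deterministic function of
`b`, and the classical objective-perturbation argument gives epsilon-DP
provided every row satisfies the norm bound. Rows that violate it raise an
error with the offending row indices — they are never silently clipped,
because clipping changes the estimand without telling the analyst.

Two perturbation regimes are available, both epsilon-DP:

* plain: `eps_eff = epsilon - 2 log(1 + c / (n lambda))`, `Delta = 0`, with
  `c = R^2/4` the curvature bound of the logistic loss under the row-norm
  constraint;
* extra ridge: `Delta = c / (n (e^{epsilon/4} - 1)) - lambda` and
  `eps_eff = epsilon / 2`.

The textbook presentation uses the plain regime and falls back to the second
only when the adjustment is non-positive. `dpcc` instead uses whichever
regime yields the **larger effective epsilon**. With the weak default ridge
this matters: at `lambda = 1/n` and `R = 13` the plain adjustment costs about
7.5 units of epsilon, so the fall-back-only rule produces `eps_eff = 2.46` at
`epsilon = 10` but `eps_eff = 2.5` at `epsilon = 5` — the privacy-utility
curve would be non-monotone for a purely algebraic reason. Choosing the
better regime restores monotone `eps_eff = epsilon/2` throughout the moderate
range while converging to the unadjusted objective for large epsilon.

### Parameters that matter

* `epsilon` (> 0, unitless privacy loss): the swept quantity. The default
  grid is `[10, 5, 2, ln 3, 1, ln 2, 0.25, 0.1, 0.05, 0.025, 0.01]`,
  approximately log-spaced and spanning high, medium, and low privacy-loss
  ranges (`default_epsilon_grid()`).
* `data_norm` (`R`): the assumed maximum row L2 norm. The default follows
  the rule implemented in `compute_data_norm()`: with `p` binary or min-max
  normalized continuous predictors, every row has norm at most
  `sqrt(p) <= p`, and `p` is used as the (loose) bound. The tighter
  `sqrt(p)` is available via `tight = TRUE`; a looser bound adds
  proportionally more noise, and this choice materially affects how early
  odds ratios diverge. The intercept's constant 1 counts toward the
  realized row norm; since `sqrt(p + 1) <= p` for `p >= 2`, the default
  bound remains valid for any model with at least two predictors
  (single-predictor models need an explicit `data_norm`).
* `regularization` (`lambda`, default `1/n`): a weak ridge that keeps the
  private objective strongly convex while approaching the unregularized
  maximum-likelihood fit as `n` grows. Because continuous covariates are
  min-max normalized to `[0, 1]`, their coefficients are weakly identified
  and visibly shrunk at small `n`; at the fixture's `n = 22 165` the
  ridge-vs-MLE gap is below 3% on the odds-ratio scale.
* `seed`: every noise draw is seeded. `default_seeds()` returns four
  predetermined seeds (a primary plus three sensitivity seeds), declared in
  code rather than drawn at runtime, so that noise realizations cannot be
  cherry-picked — the "seed p-hacking" risk that motivates seed averaging.

### Confidence intervals for private estimates

The package reports Wald intervals for DP coefficients computed from the
observed information of the *non-private* logistic likelihood evaluated at
the private point estimates, flagged
`ci_basis = "nonprivate_information_at_private_estimate"`. This is the only
construction that adds no privacy cost; a fully private interval would
require further budget. These intervals describe curvature at the released
point, not sampling-plus-noise uncertainty, and should be read accordingly.

## Non-private estimation

`fit_logistic()` is ordinary maximum-likelihood logistic regression
(IRLS via `stats::glm`) with explicit rank and separation checks.
`contingency_or()` implements the unadjusted 2x2 odds ratio with the Woolf
interval and an optional Haldane-Anscombe 0.5 correction applied only when a
zero cell occurs (and flagged). `prevalence_ratio()` is the case-to-control
prevalence ratio with the Katz log-scale interval
`SE = sqrt(1/a - 1/n1 + 1/b - 1/n2)` by default; the published table this
package emulates prints interval widths consistent with the
covariate-independent `SE = sqrt(1/n1 + 1/n2)` instead, so that variant is
available behind `constant_se = TRUE`. Two-sided p-values use the standard
normal reference; no multiplicity adjustment is applied.

## Matching

`propensity_scores()` models case membership on the baseline covariates
(sex, ethnicity, COPD, 1-year exacerbation and corticosteroid history,
smoking indicators, normalized age and asthma duration).
`knn_match()` is greedy nearest-neighbor matching without replacement under
a caliper (default 0.1 on the raw propensity scale; a logit-scale option
exists). Design choices where the method description is open:

* Cases are processed in a seed-controlled random permutation: no stated
  order exists, a randomized-but-seeded order avoids systematic bias and is
  reproducible.
* Ties between equidistant controls break toward the lower control row
  index, making results deterministic.
* With `ratio > 1`, controls are taken nearest-first until the ratio or the
  caliper is exhausted; partial matches are kept.
* Cases with no in-caliper control are reported unmatched and dropped from
  matched analyses.

Balance is summarized by the standardized mean difference,
`(mean_1 - mean_0) / sqrt((var_1 + var_0)/2)` with `p(1-p)` arm variances
for binary covariates; SMD < 0.1 is the conventional balance threshold. A
zero pooled variance with unequal means yields an infinite sentinel rather
than an error.

## The evaluation framework

`epsilon_sweep()` fits the DP model at every (epsilon, seed) cell and
compares against the non-private reference fit. Because a given seed fixes
both the noise direction and the underlying Gamma variate, noise draws are
coupled across epsilon values for the same seed — per-seed degradation
curves are smooth in epsilon, which mirrors running an analysis pipeline
with one fixed seed.

**Divergence epsilon.** A private odds ratio "diverges" when its point
estimate falls outside the reference 95% CI. Scanning the grid in descending
order, the per-seed onset is the largest grid epsilon at which this happens;
transient re-entries at smaller epsilon do not reset the onset. Across seeds
the summary reports the min/max onsets and their width. Rare covariates
(CKD at ~1% prevalence in the fixture) have small effective information, so
their coefficients absorb more of the objective noise and diverge at larger
epsilon than prevalent ones — the qualitative ordering the test suite
asserts.

**Seed aggregation.** `seed_aggregate()` averages (or takes the median of)
log odds ratios across seeds per (covariate, epsilon). The objective noise
has mean zero, so seed averages converge to the noise-free regularized fit,
not to any single lucky draw — the package's mitigation for seed p-hacking.
Aggregated CI bounds are computed by the same statistic on the log scale and
flagged `"descriptive"`; they are not valid intervals.

**Attribution and performance.** All models here are linear-logistic, so
SHAP values are computed exactly: `phi_ij = beta_j (x_ij - mean(x_j))` on
the log-odds scale, with per-row additivity to `logit_i - mean(logit)`.
Calibration and discrimination use the Brier score and the Mann-Whitney
ROC AUC (ties counted one half). The Brier score is sensitive to outcome
prevalence, so it is reported per analysis and never compared across designs
with different case fractions (e.g. adjusted versus matched).

## The synthetic cohort generator

`table1_default_spec()` encodes the published per-arm margins: binary
prevalences for the thirteen analysis covariates plus a death indicator,
three-level smoking probabilities, and per-arm normal moments for age and
asthma duration. `generate_cohort()` draws covariates **independently within
arm** (only marginal prevalences are published; an analyst wanting
correlation can post-process, but the default states exactly what is known),
then min-max normalizes continuous columns using pooled bounds — pooled
because matching operates on the combined cohort. Age >= 60 is generated as
a binary covariate directly from the published age-band proportions rather
than by thresholding simulated age, so the printed margin is matched
exactly. The death indicator is generated per arm and used only by the
death-exclusion sensitivity flag.

Three inconsistencies in the source table are resolved explicitly: the CKD
control prevalence uses the printed 0.69% (the printed count is inconsistent
with the cohort margins); BMI >= 30 in controls uses the printed count 5735
(the printed percentage is inconsistent with the count); smoking level
probabilities use the printed percentages, which sum to exactly 100.00 in
both arms, rather than the internally inconsistent counts.

What the generator deliberately does **not** emulate: covariate
correlations (including age vs age-band consistency — simulated continuous
age is independent of the age >= 60 indicator), any outcome model linking
covariates to case status within the fixed-margin design, missing data, or
death times. Tests passing on this fixture therefore demonstrate mechanism
behavior under the published margins, not on real linked records; in
particular, matching on continuous age balances age but not the
independently generated age >= 60 indicator, which is why balance assertions
target the covariates actually in the propensity model.

`generate_outcome_cohort()` is the complementary harness: covariates from
single-arm marginals and outcome from `Bernoulli(plogis(intercept + X beta))`
with the truth retained, enabling the coverage tests of the Wald machinery.

## Numerical choices

* The perturbed objective is minimized by damped Newton with step halving;
  it is strongly convex, so convergence is global. The gradient tolerance is
  1e-10; typical fits take under ten iterations.
* Stable `log(1 + e^t)` evaluation guards against overflow when the noise
  term pushes coefficients to large magnitudes at small epsilon.
* At `epsilon <= 0.05` the private coefficients saturate: the minimizer is
  approximately `-b / (n lambda_total)` with norm close to `4 d / R`
  independent of epsilon, so the degradation curve flattens at the grid
  tail (and can show one spurious adjacent inversion there — MC noise on a
  plateau).
* Wald intervals use `z = 1.959964`; the accountant recomputes its total as
  an exact sum over entries on every update, so totals cannot drift.
* Matching uses an expanding two-pointer search over score-sorted controls
  with equal-score runs resolved by lowest original index; it is exact, not
  approximate.

## Privacy accounting and trust models

`privacy_ledger()` implements sequential composition: the total privacy loss
of multiple releases is the sum of their epsilons, capped by a budget;
releases that would exceed it are refused with the ledger unchanged. The
default grid costs `20.227` per seed if every cell is released, which is why
`run_pipeline()` supports two presets mirroring common governance
scenarios: `"remote_query"` (analysts never see microdata; descriptive
counts are Laplace-noised and charged, as is every sweep cell) and the
default `"sde"` (analysts work inside a secure environment; only final
released outputs are charged). `empirical_epsilon_check()` complements the
theory with an empirical audit: it runs the Laplace count mechanism on two
neighboring datasets and verifies that no well-populated histogram bin's
log-density ratio exceeds epsilon beyond Monte-Carlo error.

## Problem sizes used by the test suite

The bundled checks run the full published-margin fixture (n = 22 165) for
matching balance (20 seeds) and the epsilon sweep (50 seeds across the
11-point grid), a 20 000-row five-covariate cohort for the
epsilon-to-infinity limit, and 200 replicates of a 4000-row known-truth
cohort for CI coverage. These sizes give Monte-Carlo error comfortably below
the asserted tolerances while keeping a full run in the low minutes on one
CPU.

## Known limitations

* Epsilon-DP only: no (epsilon, delta)-DP, Gaussian mechanism, Renyi
  accounting, or local-DP microdata perturbation. DP applies to regression
  outputs; SHAP, Brier, and AUC are never themselves privatized.
* The DP confidence intervals are point-estimate diagnostics (see above),
  matching the reference-library convention, not private uncertainty
  statements.
* Matching is greedy, not optimal; no Mahalanobis/exact matching or
  weighting.
* The matched analysis refits ordinary logistic regression on the matched
  subset with the matching covariates retained in the linear predictor
  (configurable via the covariate list); conditional logistic regression is
  out of scope.
* Published real-data odds ratios and exact divergence epsilons are not
  reproducible from synthetic margins; the package asserts the qualitative
  structure (balance, degradation monotonicity, AUC floor, rare-vs-common
  divergence ordering) instead.
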