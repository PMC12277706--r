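# dpcc — differentially private case-control analysis

`dpcc` is an R package for studying what differential privacy (DP) does to a
case-control study of electronic health records: to the odds ratios, their
confidence intervals, covariate balance after propensity-score matching, and
overall model calibration and discrimination — as a function of the privacy
parameter epsilon and of the random seed that drives the DP noise.

It is aimed at biostatisticians and data-governance teams who need to pick an
epsilon and a privacy budget for observational analyses released from secure
data environments, and who want a reproducible sandbox for that decision
rather than one-off experiments on access-controlled data.

## What is inside

**The private estimator.** An epsilon-DP regularized logistic regression by
objective perturbation. The released coefficients minimize

    (1/n) Σ_i log(1 + exp(-y_i x_i' β)) + (λ + Δ)/2 ||β||² + b'β / n

where the noise vector `b` has direction uniform on the sphere and norm drawn
from `Gamma(d, 2R/ε_eff)`; `R` is the assumed bound on any row's L2 norm
(`compute_data_norm()`: `p` for `p` binary or min-max-normalized predictors),
and `ε_eff` is the standard objective-perturbation adjustment of ε for the
ridge strength. Rows exceeding `R` raise an error, never silent clipping.

**The rest of the pipeline.** The Laplace mechanism plus an empirical
epsilon audit; a sequential-composition privacy accountant with a hard
budget; maximum-likelihood reference fits with Wald odds ratios;
contingency-table ORs and case-to-control prevalence ratios; greedy 1:k
nearest-neighbor propensity matching without replacement under a caliper,
with standardized-mean-difference balance tables; an epsilon sweep across
predetermined seeds with divergence-epsilon detection (the largest grid
epsilon at which a private OR leaves the reference 95% CI), seed averaging,
exact linear SHAP attributions, Brier score, and ROC AUC; and a synthetic
cohort generator that reproduces the covariate margins of a published
asthma-exacerbation cohort (2714 cases / 19 451 controls), so everything
runs without any data access.

All user-facing functions take a data frame first and return tibbles;
results have `tidy()`/`glance()` methods and `plot_forest()`,
`plot_balance()`, `plot_performance()` / `autoplot()` builders.

## Worked example

```r
library(dpcc)
library(dplyr)

cohort <- table1_default_spec() |>
  generate_cohort(seed = 1) |>
  expand_smoking()

# non-private reference odds ratios (adjusted model, 13 risk factors)
fit <- fit_logistic(cohort, adjusted_covariates())
odds_ratios(fit) |> filter(name %in% c("copd", "female", "ckd"))
#>   name    beta     se    or ci_low ci_high        p
#> 1 female 0.301 0.0446  1.35   1.24    1.47 1.38e-11
#> 2 ckd    0.453 0.221   1.57   1.02    2.43 4.08e- 2
#> 3 copd   1.31  0.0672  3.71   3.25    4.23 7.35e-85

# the same model released with epsilon = ln(2)
dp_fit <- dp_logistic_regression(
  cohort, privacy_params(epsilon = log(2), seed = 20), adjusted_covariates())
odds_ratios(dp_fit) |> filter(name %in% c("copd", "female", "ckd")) |>
  select(name, or, ci_low, ci_high, epsilon)
#>   name      or ci_low ci_high epsilon
#> 1 female 0.710  0.657   0.767   0.693
#> 2 ckd    5.57   4.00    7.74    0.693
#> 3 copd   2.40   2.10    2.74    0.693
```

At ε = ln(2) the noise has visibly distorted the estimates: the female-sex
OR flips below 1, and CKD — the rarest covariate, hence the least
information in the likelihood — swings from 1.57 to 5.57. The DP intervals
here are Wald intervals from the non-private information evaluated at the
private estimates (`ci_basis` column): curvature diagnostics, not private
uncertainty statements.

```r
# 1:1 propensity matching with a 0.1 caliper
scores <- propensity_scores(cohort)
m <- knn_match(scores, cohort$case, ratio = 1, caliper = 0.1, seed = 7)
m
#> 1:1 caliper 0.1 matching: 2698 cases matched to 2698 controls; 16 cases unmatched
balance_table(cohort, m, covariates = propensity_covariates()) |>
  summarise(max_abs_smd_after = max(abs(smd_after)))
#> max |SMD| after matching: 0.0526   (all baseline covariates below the 0.1 threshold)

# sweep epsilon across the four predetermined seeds and locate divergences
sw <- epsilon_sweep(cohort, adjusted_covariates(), seeds = default_seeds())
divergence_epsilon(sw) |>
  select(name, n_seeds_diverged, range_low, range_high, range_width) |>
  arrange(desc(range_high)) |> head(4)
#>   name              n_seeds_diverged range_low range_high range_width
#> 1 cardinal_symptoms                4      5            10        5
#> 2 ckd                              4     10            10        0
#> 3 diabetes                         3      0.25         10        9.75
#> 4 ocs_rx_1y                        4      2            10        8
```

`range_high` is the largest grid epsilon at which the private OR first left
the reference CI for some seed, `range_low` the smallest across seeds: CKD
(prevalence ~1%) diverges already at ε = 10 in every seed, while prevalent,
well-identified covariates hold on longer. Descriptive statistics follow the
same grammar:

```r
prevalence_ratio(403, 2714, 862, 19451)   # COPD, cases vs controls
#>   pr   ci_low ci_high  a    n1    b    n2   se_method
#> 1 3.35   3.00    3.74  403  2714  862  19451 katz
```

`run_pipeline(run_config(...), out_dir)` chains all stages
(simulate → fit → match → sweep → report) and writes effect tables, balance
tables, sweep exports, a divergence summary, the privacy ledger, and a
manifest; identical configs produce byte-identical artifacts.

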