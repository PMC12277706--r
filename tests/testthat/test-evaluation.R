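test_that("the default grid is the documented descending set", {
  g <- default_epsilon_grid()
  expect_equal(g, c(10, 5, 2, log(3), 1, log(2), 0.25, 0.1, 0.05, 0.025, 0.01))
  expect_true(all(diff(g) < 0))
})

test_that("epsilon sweeps have full cardinality and are seed-deterministic", {
  d <- small_cohort(seed = 41)
  covs <- c("exposure", "comorb", "female")
  sw <- epsilon_sweep(d, covs, grid = c(5, 1, 0.1), seeds = c(7, 7, 9))
  expect_equal(nrow(sw$estimates), 3 * 3 * 3)
  # duplicate seeds give identical estimate columns
  e7a <- sw$estimates[sw$estimates$seed == 7, ]
  expect_equal(nrow(e7a), 2 * 3 * 3)
  wide <- tidyr::pivot_wider(sw$estimates, id_cols = c("name", "epsilon"),
                             names_from = "seed", values_from = "beta",
                             values_fn = list)
  expect_true(all(vapply(wide$`7`, function(v) length(unique(v)) == 1, logical(1))))
  expect_equal(nrow(sw$reference), 3)
})

test_that("at enormous epsilon the private ORs sit on the reference", {
  # n large enough that the weak default ridge (1/n) is negligible
  d <- generate_cohort(small_spec(n_cases = 3000L, n_controls = 15000L), seed = 42)
  covs <- c("exposure", "comorb", "female")
  sw <- epsilon_sweep(d, covs, grid = 1e6, seeds = 1L)
  merged <- dplyr::inner_join(sw$estimates, sw$reference, by = "name",
                              suffix = c("", "_ref"))
  expect_true(all(abs(merged$or / merged$or_ref - 1) < 0.02))
})

test_that("sweep cells record fit failures without aborting", {
  d <- small_cohort(seed = 43)
  d$wide <- d$age * 3 # exceeds the data_norm bound for these covariates
  sw <- epsilon_sweep(d, c("exposure", "wide"), grid = c(1), seeds = 1L,
                      data_norm = 1.2)
  expect_true(all(sw$estimates$failed))
})

test_that("sweeps charge the ledger per release and stop at the budget", {
  d <- small_cohort(seed = 44)
  led <- privacy_ledger(6)
  sw <- epsilon_sweep(d, "exposure", grid = c(2, 1), seeds = c(1L, 2L), ledger = led)
  expect_equal(sw$ledger$total_spent, 2 * 2 + 1 * 2)
  expect_error(
    epsilon_sweep(d, "exposure", grid = c(2, 1), seeds = c(1L, 2L),
                  ledger = privacy_ledger(3)),
    class = "dpcc_budget_error")
})

test_that("divergence onset scans the grid descending and keeps the first exit", {
  # hand-built sweep: reference CI (0.9, 1.1); seed 1 exits at 5 and re-enters;
  # seed 2 exits at 2 only; seed 3 never exits
  grid <- c(5, 2, 1)
  ref <- tibble::tibble(name = "x", beta = 0, se = 0.05, or = 1,
                        ci_low = 0.9, ci_high = 1.1, p = 1)
  est <- tidyr::expand_grid(name = "x", epsilon = grid, seed = 1:3)
  est$or <- c(1.5, 1.0, 1.0, # eps 5: seeds 1..3
              1.0, 1.3, 1.0, # eps 2
              1.0, 1.4, 1.05) # eps 1
  est$failed <- FALSE
  sw <- structure(list(estimates = est, reference = ref, grid = grid,
                       seeds = 1:3, ledger = NULL), class = "sweep_result")
  div <- divergence_epsilon(sw)
  expect_equal(div$onsets[[1]][["1"]], 5)
  expect_equal(div$onsets[[1]][["2"]], 2)
  expect_true(is.na(div$onsets[[1]][["3"]]))
  expect_equal(div$range_low, 2)
  expect_equal(div$range_high, 5)
  expect_equal(div$range_width, 3)
  expect_equal(div$n_seeds_diverged, 2L)
  expect_error(divergence_epsilon(sw, "ghost"), class = "dpcc_key_error")

  # all inside: none sentinel; all onsets equal: width 0
  est2 <- est; est2$or <- 1
  sw2 <- sw; sw2$estimates <- est2
  div2 <- divergence_epsilon(sw2)
  expect_true(is.na(div2$range_low) && is.na(div2$range_width))
  est3 <- est; est3$or <- rep(c(1.5, 1, 1), each = 3)
  sw3 <- sw; sw3$estimates <- est3
  div3 <- divergence_epsilon(sw3)
  expect_equal(div3$range_width, 0)
})

test_that("range_width equals range_high - range_low on a real sweep", {
  d <- small_cohort(seed = 45)
  sw <- epsilon_sweep(d, c("exposure", "comorb"), grid = c(2, 0.5, 0.05),
                      seeds = 1:4)
  div <- divergence_epsilon(sw)
  ok <- !is.na(div$range_width)
  expect_equal(div$range_width[ok], (div$range_high - div$range_low)[ok],
               tolerance = 1e-12)
})

test_that("seed aggregation averages on the log-OR scale", {
  grid <- c(1)
  ref <- tibble::tibble(name = "x", beta = 0.3, se = 0.05, or = exp(0.3),
                        ci_low = exp(0.2), ci_high = exp(0.4), p = 0.01)
  est <- tibble::tibble(name = "x", epsilon = 1, seed = 1:2,
                        beta = c(0.2, 0.4), se = 0.05,
                        or = exp(c(0.2, 0.4)),
                        ci_low = exp(c(0.1, 0.3)), ci_high = exp(c(0.3, 0.5)),
                        p = 0.05, failed = FALSE)
  sw <- structure(list(estimates = est, reference = ref, grid = grid,
                       seeds = 1:2, ledger = NULL), class = "sweep_result")
  agg <- seed_aggregate(sw, "mean")
  expect_equal(agg$beta, 0.3)
  expect_equal(agg$or, exp(0.3))
  expect_equal(agg$ci_low, exp(0.2))
  expect_equal(agg$ci_basis, "descriptive")
  # duplicated identical seeds: aggregate equals the single estimate
  est2 <- est; est2$beta <- 0.25; est2$or <- exp(0.25)
  sw2 <- sw; sw2$estimates <- est2
  expect_equal(seed_aggregate(sw2, "median")$beta, 0.25)
  sw1 <- sw; sw1$seeds <- 1L
  expect_error(seed_aggregate(sw1), class = "dpcc_usage_error")
})

test_that("many-seed aggregates converge to the noise-free fit at large epsilon", {
  d <- small_cohort(seed = 46)
  covs <- c("exposure", "female")
  sw <- epsilon_sweep(d, covs, grid = c(50), seeds = 1:100)
  agg <- seed_aggregate(sw, "mean")
  # the objective noise has mean zero, so seed averages home in on the
  # noise-free regularized fit
  target <- fit_logistic_ridge(d, covs)[agg$name]
  sds <- sw$estimates |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(se_mc = stats::sd(.data$beta) / sqrt(100))
  merged <- dplyr::inner_join(agg, sds, by = "name")
  expect_true(all(abs(merged$beta - target) < 4 * merged$se_mc + 0.005))
})

test_that("linear SHAP is centered, additive, and matches exact Shapley values", {
  d <- small_cohort(seed = 47)
  covs <- c("exposure", "comorb", "female", "age")
  fit <- fit_logistic(d, covs)
  phi <- shap_linear(fit, d)
  expect_equal(dim(phi), c(nrow(d), 4L))
  # a row at the feature means gets zero attribution
  X <- as.matrix(d[covs])
  means <- colMeans(X)
  # additivity: rows sum to logit - mean logit
  eta <- drop(cbind(1, X) %*% coef(fit))
  expect_equal(unname(rowSums(phi)), eta - (attr(phi, "baseline")) , tolerance = 1e-9)
  expect_equal(attr(phi, "baseline"), unname(coef(fit)[1] + sum(means * coef(fit)[-1])),
               tolerance = 1e-12)
  # exact Shapley enumeration oracle on a 4-feature row
  beta <- coef(fit)[-1]
  x_row <- X[5, ]
  oracle <- oracle_shapley_linear(beta, x_row, means)
  expect_equal(unname(phi[5, ]), oracle, tolerance = 1e-9)
  imp <- shap_importance(phi)
  expect_equal(sort(imp$name), sort(covs))
  expect_true(all(diff(imp$mean_abs_shap) <= 0))
})

test_that("brier score and ROC AUC match closed forms and a reference implementation", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier_score(c(0.9, 0.2, 0.7), c(1, 0, 1)), (0.01 + 0.04 + 0.09) / 3)
  expect_error(brier_score(c(0.5), c(1, 0)), class = "dpcc_usage_error")

  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "dpcc_usage_error")
  skip_if_not_installed("pROC")
  sc <- withr::with_seed(9, runif(200))
  y <- withr::with_seed(10, rbinom(200, 1, plogis(2 * sc - 1)))
  expect_equal(roc_auc(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("forest export writes tidy files that round-trip", {
  d <- small_cohort(seed = 48)
  covs <- c("exposure", "female")
  sw <- epsilon_sweep(d, covs, grid = c(2, 0.5), seeds = 1:2)
  div <- divergence_epsilon(sw)
  dir <- withr::local_tempdir()
  forest_export(sw, dir, div)
  est <- readr::read_csv(file.path(dir, "sweep_estimates.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(est), 2 * 2 * 2) # covariates x grid x seeds
  expect_true(all(c("name", "epsilon", "seed", "or", "ci_low", "ci_high",
                    "diverged") %in% names(est)))
  sw2 <- read_sweep(dir)
  expect_equal(sw2$estimates$or, sw$estimates$or)
  expect_equal(sw2$reference$beta, sw$reference$beta)
  expect_equal(sw2$grid, sw$grid)
  expect_equal(sw2$seeds, sw$seeds)
})

test_that("plot builders return ggplot objects", {
  d <- small_cohort(seed = 49)
  sw <- epsilon_sweep(d, c("exposure", "female"), grid = c(2, 0.5), seeds = 1:2)
  expect_s3_class(plot_forest(sw), "ggplot")
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
  sc <- propensity_scores(d, c("exposure", "comorb", "female", "age"))
  m <- knn_match(sc, d$case, seed = 1)
  expect_s3_class(plot_balance(balance_table(d, m)), "ggplot")
  perf <- performance_sweep(d, c("exposure", "female"), grid = c(2, 0.5), seeds = 1:2)
  expect_s3_class(plot_performance(perf), "ggplot")
})
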