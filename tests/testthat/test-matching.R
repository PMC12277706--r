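test_that("greedy caliper matching reproduces the hand-enumerated example", {
  scores <- c(0.30, 0.50, 0.70, 0.29, 0.31, 0.52, 0.69, 0.95)
  outcome <- c(1, 1, 1, 0, 0, 0, 0, 0)
  m <- knn_match(scores, outcome, ratio = 1, caliper = 0.1, seed = 1)
  expect_equal(length(m$unmatched_cases), 0)
  expect_equal(nrow(m$pairs), 3)
  # case 0.30 ties 0.29/0.31 -> lower index (row 4) wins
  expect_equal(m$pairs$control_id[m$pairs$case_id == 1], 4)
  expect_equal(m$pairs$control_id[m$pairs$case_id == 2], 6)
  expect_equal(m$pairs$control_id[m$pairs$case_id == 3], 7)
  expect_false(8 %in% m$pairs$control_id) # 0.95 is out of caliper, unused
})

test_that("matching agrees with a brute-force greedy oracle across random cases", {
  for (seed in 1:5) {
    n1 <- 8; n0 <- 20
    sc <- withr::with_seed(seed, round(runif(n1 + n0), 2))
    out <- rep(c(1, 0), c(n1, n0))
    m <- knn_match(sc, out, ratio = 2, caliper = 0.15, seed = seed)
    case_order <- withr::with_seed(seed, sample(seq_len(n1)))
    oracle <- oracle_greedy_match(sc[seq_len(n1)], sc[n1 + seq_len(n0)],
                                  ratio = 2, caliper = 0.15, case_order = case_order)
    got <- lapply(split(m$pairs$control_id - n1, m$pairs$case_id),
                  function(x) sort(unname(x)))
    want <- setNames(lapply(oracle, function(p) sort(p$controls)),
                     vapply(oracle, function(p) as.character(p$case), character(1)))
    expect_equal(got[order(as.integer(names(got)))],
                 want[order(as.integer(names(want)))])
  }
})

test_that("matching invariants hold: no reuse, caliper compliance, case subset", {
  d <- small_cohort(seed = 31)
  sc <- propensity_scores(d, c("exposure", "comorb", "female", "age"))
  for (ratio in c(1L, 2L, 4L)) {
    m <- knn_match(sc, d$case, ratio = ratio, caliper = 0.05, seed = ratio)
    expect_equal(anyDuplicated(m$pairs$control_id), 0L)
    expect_true(all(m$pairs$distance <= 0.05))
    expect_true(all(table(m$pairs$case_id) <= ratio))
    expect_true(all(m$pairs$case_id %in% which(d$case == 1)))
    expect_true(all(m$pairs$control_id %in% which(d$case == 0)))
    expect_setequal(c(unique(m$pairs$case_id), m$unmatched_cases),
                    which(d$case == 1))
  }
})

test_that("degenerate calipers and score ties behave as documented", {
  # caliper smaller than every case-control gap: all cases unmatched
  m <- knn_match(c(0.9, 0.1, 0.2), c(1, 0, 0), caliper = 0.01, seed = 1)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_cases, 1L)
  # identical scores everywhere: every case matched at distance zero
  m2 <- knn_match(rep(0.5, 10), rep(c(1, 0), 5), ratio = 1, caliper = 0.1, seed = 2)
  expect_equal(length(m2$unmatched_cases), 0)
  expect_true(all(m2$pairs$distance == 0))
  expect_error(knn_match(c(0.5, 0.6), c(1, 1), caliper = 0.1),
               class = "dpcc_usage_error")
})

test_that("matching is deterministic given a seed", {
  d <- small_cohort(seed = 32)
  sc <- propensity_scores(d, c("exposure", "comorb", "female", "age"))
  m1 <- knn_match(sc, d$case, seed = 5)
  m2 <- knn_match(sc, d$case, seed = 5)
  expect_identical(m1$pairs, m2$pairs)
})

test_that("standardized mean differences match closed forms", {
  x <- c(rep(1, 50), rep(0, 50), rep(1, 30), rep(0, 70))
  g <- rep(c(1, 0), each = 100)
  expect_equal(smd(x, g), 0.2 / sqrt((0.25 + 0.21) / 2), tolerance = 1e-12)
  expect_equal(smd(rep(1, 20), rep(c(1, 0), 10)), 0)
  # zero pooled variance with unequal means: infinite sentinel
  expect_identical(smd(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(5, 5))), Inf)
  expect_error(smd(1:3, c(1, 1, 1)), class = "dpcc_usage_error")
})

test_that("balance tables report before/after SMDs with exact-balance zeros", {
  d <- small_cohort(seed = 33)
  bt <- balance_table(d)
  expect_false("smd_after" %in% names(bt))
  expect_gt(bt$smd_before[bt$name == "exposure"], 0.2)
  # self-matched data (each case matched to an identical clone) balances exactly
  cases <- d[d$case == 1, ]
  clones <- dplyr::mutate(cases, case = 0)
  dd <- dplyr::bind_rows(cases, clones)
  n1 <- nrow(cases)
  m <- structure(list(pairs = tibble::tibble(
    case_id = seq_len(n1), control_id = n1 + seq_len(n1),
    score_case = 0.5, score_control = 0.5, distance = 0),
    unmatched_cases = integer(), ratio = 1L, caliper = 0.1,
    scores = rep(0.5, 2 * n1)), class = "match_result")
  bt2 <- balance_table(dd, m)
  expect_true(all(bt2$smd_after == 0))
})

test_that("COPD carries the largest pre-matching imbalance among baseline covariates", {
  d <- expand_smoking(generate_cohort(table1_default_spec(), seed = 2))
  bt <- balance_table(d, covariates = propensity_covariates())
  expect_equal(bt$name[which.max(abs(bt$smd_before))], "copd")
})

test_that("matching on confounded data reduces covariate imbalance", {
  spec <- outcome_model_spec(
    intercept = -2.2, coefficients = c(conf1 = 1.2, conf2 = 0.8), n = 3000,
    covariates = list(covariate_spec("conf1", "binary", prev = 0.3),
                      covariate_spec("conf2", "binary", prev = 0.5)))
  worse <- 0
  for (seed in 1:10) {
    d <- generate_outcome_cohort(spec, seed = seed)
    sc <- propensity_scores(d, c("conf1", "conf2"))
    m <- knn_match(sc, d$case, ratio = 1, caliper = 0.1, seed = seed)
    bt <- balance_table(d, m, covariates = c("conf1", "conf2"))
    if (mean(abs(bt$smd_after)) >= mean(abs(bt$smd_before))) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("DP propensity scores stay in (0,1) and approach the non-private ones", {
  d <- small_cohort(seed = 34)
  covs <- c("exposure", "comorb", "female", "age")
  sc <- propensity_scores(d, covs)
  res <- dp_propensity_scores(d, privacy_params(1e6, seed = 1), covs)
  # epsilon -> infinity limit is the noise-free regularized score model ...
  ridge_scores <- plogis(drop(cbind(1, as.matrix(d[covs])) %*%
                                fit_logistic_ridge(d, covs)))
  expect_lt(max(abs(res$scores - ridge_scores)), 1e-6)
  # ... which tracks the non-private scores up to the weak-ridge bias
  expect_lt(max(abs(res$scores - sc)), 0.1)
  res2 <- dp_propensity_scores(d, privacy_params(0.01, seed = 1), covs)
  expect_true(all(res2$scores > 0 & res2$scores < 1))
  led <- privacy_ledger(2)
  res3 <- dp_propensity_scores(d, privacy_params(1, seed = 1), covs, ledger = led)
  expect_equal(res3$ledger$total_spent, 1)
  expect_error(propensity_scores(d, c("exposure", "ghost")),
               class = "dpcc_config_error")
})
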