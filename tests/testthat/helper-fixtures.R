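# Shared fixtures and independent oracles used across test files.

# A scaled-down case-control cohort with a handful of covariates, fast to
# generate and fit.
small_spec <- function(n_cases = 300L, n_controls = 1500L) {
  cohort_spec(
    n_cases = n_cases, n_controls = n_controls, seed = 42L,
    covariates = list(
      covariate_spec("exposure", "binary", prev_cases = 0.30, prev_controls = 0.10),
      covariate_spec("comorb", "binary", prev_cases = 0.20, prev_controls = 0.15),
      covariate_spec("female", "binary", prev_cases = 0.60, prev_controls = 0.55),
      covariate_spec("age", "continuous",
                     mean_cases = 60, sd_cases = 8, mean_controls = 56, sd_controls = 8)
    )
  )
}

small_cohort <- function(seed = 1L, ...) generate_cohort(small_spec(...), seed = seed)

# Independent logistic-regression oracle: plain Newton-Raphson on the
# unpenalized log-likelihood, written without reference to the package
# implementation (which delegates to stats::glm).
oracle_logistic <- function(X, y, tol = 1e-12, max_iter = 50) {
  X <- cbind(1, X)
  beta <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    g <- drop(crossprod(X, y - mu))
    H <- crossprod(X * sqrt(mu * (1 - mu)))
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, vcov = solve(crossprod(X * sqrt(mu * (1 - mu)))))
}

# Exact Shapley values by enumeration over feature coalitions, for a linear
# value function v(S) = E[f(x) | x_S] under feature independence.
oracle_shapley_linear <- function(beta, x, mu) {
  d <- length(beta)
  phi <- numeric(d)
  idx <- seq_len(d)
  for (j in idx) {
    others <- setdiff(idx, j)
    for (k in 0:length(others)) {
      sets <- if (k == 0) list(integer(0)) else utils::combn(others, k, simplify = FALSE)
      w <- factorial(k) * factorial(d - k - 1) / factorial(d)
      for (S in sets) {
        vS <- sum(beta[S] * x[S]) + sum(beta[setdiff(idx, S)] * mu[setdiff(idx, S)])
        Sj <- c(S, j)
        vSj <- sum(beta[Sj] * x[Sj]) + sum(beta[setdiff(idx, Sj)] * mu[setdiff(idx, Sj)])
        phi[j] <- phi[j] + w * (vSj - vS)
      }
    }
  }
  phi
}

# Brute-force greedy caliper matching on a handful of units, mirroring the
# documented tie rules, for cross-checking knn_match on tiny inputs.
oracle_greedy_match <- function(case_scores, ctrl_scores, ratio, caliper, case_order) {
  used <- logical(length(ctrl_scores))
  pairs <- list()
  for (i in case_order) {
    taken <- integer()
    for (r in seq_len(ratio)) {
      d <- abs(ctrl_scores - case_scores[i])
      d[used] <- Inf
      if (min(d) > caliper) break
      j <- which(d == min(d))[1] # lowest index among ties
      used[j] <- TRUE
      taken <- c(taken, j)
    }
    if (length(taken)) pairs[[length(pairs) + 1]] <- list(case = i, controls = taken)
  }
  pairs
}
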