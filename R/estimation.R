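#' Fit the non-private logistic regression reference model
#'
#' Maximum-likelihood logistic regression of case status on the selected
#' covariates (iteratively reweighted least squares via [stats::glm()]),
#' with explicit rank and separation checks: a rank-deficient design raises a
#' design error and non-convergence or (quasi-)complete separation raises a
#' convergence error rather than returning unstable coefficients.
#'
#' @param data a cohort data frame with a 0/1 `case` column and no missing
#'   values.
#' @param covariates character vector of covariate columns; default: all
#'   binary and continuous covariates.
#' @return a `cc_logit` object (a `glm` subclass) carrying the covariate list;
#'   supports [odds_ratios()], `tidy()`, `glance()`, `coef()`, `vcov()`,
#'   `predict()`.
#' @export
fit_logistic <- function(data, covariates = NULL) {
  des <- build_design(data, covariates, intercept = TRUE)
  qrX <- qr(des$X)
  if (qrX$rank < ncol(des$X)) {
    dep <- colnames(des$X)[qrX$pivot[(qrX$rank + 1):ncol(des$X)]]
    abort(paste0("design matrix is rank deficient (linearly dependent: ",
                 paste(dep, collapse = ", "), ")."),
          class = "dpcc_design_error")
  }
  df <- tibble::as_tibble(as.data.frame(des$X[, -1, drop = FALSE]))
  df$case <- des$y
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(case ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged || (separation && any(abs(coef(fit)) > 12))) {
    abort("logistic regression did not converge (possible separation).",
          class = "dpcc_convergence_error")
  }
  fit$covariates <- des$covariates
  class(fit) <- c("cc_logit", class(fit))
  fit
}

effect_table <- function(beta, se, names) {
  tibble::tibble(
    name = names,
    beta = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - WALD_Z * unname(se)),
    ci_high = exp(unname(beta) + WALD_Z * unname(se)),
    p = 2 * pnorm(-abs(unname(beta) / unname(se)))
  )
}

#' Per-covariate odds ratios with Wald 95% confidence intervals
#'
#' Exponentiated coefficients with `exp(beta -/+ 1.959964 se)` intervals and
#' two-sided normal p-values. For a DP fit the standard errors come from the
#' observed information of the (non-private) logistic likelihood evaluated at
#' the private point estimates — a "non-private CI at the private point
#' estimate", flagged in the `ci_basis` column — since a fully private interval
#' would spend additional budget.
#'
#' @param fit a [fit_logistic()] or [dp_logistic_regression()] result.
#' @param include_intercept keep the intercept row? Default `FALSE`.
#' @return a tibble with columns `name`, `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p` (plus `epsilon`, `seed`, `ci_basis` for DP fits).
#' @export
odds_ratios <- function(fit, include_intercept = FALSE) {
  UseMethod("odds_ratios")
}

#' @export
odds_ratios.cc_logit <- function(fit, include_intercept = FALSE) {
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- effect_table(beta, se, names(beta))
  if (!include_intercept) out <- out[out$name != "(Intercept)", ]
  out
}

#' @export
odds_ratios.dp_logit <- function(fit, include_intercept = FALSE) {
  beta <- fit$coefficients
  eta <- drop(fit$X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(fit$X * sqrt(w))
  covm <- tryCatch(solve(info), error = function(e) {
    diag(Inf, length(beta), length(beta))
  })
  se <- sqrt(diag(covm))
  out <- effect_table(beta, se, names(beta))
  out$epsilon <- fit$epsilon
  out$seed <- fit$seed
  out$ci_basis <- "nonprivate_information_at_private_estimate"
  if (!include_intercept) out <- out[out$name != "(Intercept)", ]
  out
}

#' Unadjusted odds ratio from a 2x2 contingency table
#'
#' `OR = ad/(bc)` with the Woolf interval, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`
#' on the log scale. When any cell is zero and `correct = TRUE`, 0.5 is added
#' to every cell (Haldane-Anscombe) and the `corrected` column flags it; a zero
#' margin without correction is a degenerate-table error.
#'
#' @param a,b,c,d non-negative cell counts: exposed cases, unexposed cases,
#'   exposed controls, unexposed controls.
#' @param correct apply the 0.5 continuity correction when a cell is zero.
#' @return a one-row tibble with `name`, `beta`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p`, `corrected`.
#' @export
contingency_or <- function(a, b, c, d, correct = TRUE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers.", class = "dpcc_parameter_error")
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (!correct) {
      abort("degenerate table: zero cell without continuity correction.",
            class = "dpcc_degenerate_table_error")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  beta <- log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
  se <- sqrt(sum(1 / cells))
  out <- effect_table(beta, se, "exposure")
  out$corrected <- corrected
  out
}

#' Case-to-control prevalence ratio of a covariate
#'
#' The ratio of covariate prevalence in cases to that in controls,
#' `pr = (a/n1) / (b/n2)`, with a log-scale Wald interval. The default
#' standard error is the Katz log method,
#' `SE = sqrt(1/a - 1/n1 + 1/b - 1/n2)`; `constant_se = TRUE` uses the
#' covariate-independent `SE = sqrt(1/n1 + 1/n2)` instead (the width pattern
#' of some published prevalence-ratio tables).
#'
#' @param a cases with the covariate; `n1` cases total.
#' @param b controls with the covariate (must be >= 1); `n2` controls total.
#' @param constant_se use the constant log-SE variant.
#' @return a one-row tibble: `name`, `pr`, `ci_low`, `ci_high`, `a`, `n1`,
#'   `b`, `n2`, `se_method`.
#' @export
prevalence_ratio <- function(a, n1, b, n2, constant_se = FALSE) {
  stopifnot(a >= 0, b >= 0, a <= n1, b <= n2)
  if (b == 0) {
    abort("prevalence ratio undefined: no exposed controls (b = 0).",
          class = "dpcc_undefined_ratio_error")
  }
  pr <- (a / n1) / (b / n2)
  se <- if (constant_se) sqrt(1 / n1 + 1 / n2) else sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  tibble::tibble(
    name = "covariate",
    pr = pr,
    ci_low = exp(log(pr) - WALD_Z * se),
    ci_high = exp(log(pr) + WALD_Z * se),
    a = a, n1 = n1, b = b, n2 = n2,
    se_method = if (constant_se) "constant" else "katz"
  )
}

#' Dichotomize covariates for parsimony
#'
#' Replaces continuous columns by threshold indicators and categorical columns
#' by level-set indicators; already-binary columns pass through unchanged. The
#' applied mapping is recorded in the `"dichotomize_rules"` attribute. Several
#' rules may target the same source column (e.g. one indicator per smoking
#' level); the source is dropped once.
#'
#' @param data a cohort data frame.
#' @param rules a list of rules, each `list(column =, new_name =, threshold =)`
#'   for continuous sources (indicator of `x >= threshold`) or
#'   `list(column =, new_name =, levels =)` for categorical sources (indicator
#'   of membership).
#' @return the dataset with binary columns replacing the originals.
#' @export
dichotomize <- function(data, rules) {
  check_cc_data(data)
  out <- data
  kinds <- covariate_kinds(data)
  drop <- character()
  for (r in rules) {
    if (!r$column %in% names(data)) {
      abort(paste0("dichotomize rule targets missing column: ", r$column),
            class = "dpcc_config_error")
    }
    x <- data[[r$column]]
    new_name <- r$new_name %||% r$column
    if (is.numeric(x) && all(x %in% c(0, 1)) && is.null(r$levels)) {
      out[[new_name]] <- as.integer(x) # already binary: idempotent
    } else if (!is.null(r$threshold)) {
      out[[new_name]] <- as.integer(as.numeric(x) >= r$threshold)
    } else if (!is.null(r$levels)) {
      out[[new_name]] <- as.integer(as.character(x) %in% r$levels)
    } else {
      abort(paste0("rule for ", r$column, " needs a threshold or level set."),
            class = "dpcc_config_error")
    }
    kinds[new_name] <- "binary"
    if (new_name != r$column) drop <- union(drop, r$column)
  }
  out <- out[setdiff(names(out), drop)]
  attr(out, "kinds") <- kinds[setdiff(names(kinds), drop)]
  attr(out, "normalized") <- attr(data, "normalized")
  attr(out, "dichotomize_rules") <- rules
  if (!inherits(out, "cc_data")) class(out) <- c("cc_data", class(out))
  out
}

#' Expand the smoking category into indicator columns
#'
#' Convenience wrapper around [dichotomize()] producing `smoking_current` and
#' `smoking_previous` indicators from the 3-level smoking factor.
#'
#' @param data a cohort with a categorical `smoking` column.
#' @return the dataset with the two indicators in place of `smoking`.
#' @export
expand_smoking <- function(data) {
  dichotomize(data, list(
    list(column = "smoking", new_name = "smoking_current", levels = "current"),
    list(column = "smoking", new_name = "smoking_previous", levels = "previous")
  ))
}

# broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cc_logit <- function(x, ...) odds_ratios(x, include_intercept = TRUE)

#' @export
tidy.dp_logit <- function(x, ...) odds_ratios(x, include_intercept = TRUE)

#' @export
glance.cc_logit <- function(x, ...) {
  tibble::tibble(
    n = length(x$y), n_cases = sum(x$y == 1),
    deviance = x$deviance, aic = x$aic,
    auc = roc_auc(x$fitted.values, x$y),
    brier = brier_score(x$fitted.values, x$y)
  )
}

#' @export
glance.dp_logit <- function(x, ...) {
  p <- plogis(drop(x$X %*% x$coefficients))
  tibble::tibble(
    n = x$n, n_cases = sum(x$y == 1), epsilon = x$epsilon,
    eps_eff = x$eps_eff, data_norm = x$data_norm,
    regularization = x$regularization + x$extra_regularization,
    auc = roc_auc(p, x$y), brier = brier_score(p, x$y)
  )
}
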