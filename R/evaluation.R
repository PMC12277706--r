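#' The default approximately log-spaced epsilon grid
#'
#' `[10, 5, 2, ln(3), 1, ln(2), 0.25, 0.1, 0.05, 0.025, 0.01]`, covering high
#' (2-10), medium (0.25-ln 3) and low (0.01-0.1) privacy-loss ranges and
#' including the commonly used ln(2) = 0.693 and ln(3) = 1.099.
#'
#' @return a strictly decreasing numeric vector of positive epsilons.
#' @export
default_epsilon_grid <- function() {
  c(10, 5, 2, log(3), 1, log(2), 0.25, 0.1, 0.05, 0.025, 0.01)
}

#' The package's predetermined evaluation seeds
#'
#' Four fixed seeds (a primary seed plus three sensitivity seeds), declared in
#' code rather than drawn at runtime so that DP noise realizations cannot be
#' cherry-picked (seed p-hacking).
#' @return integer vector of length 4.
#' @export
default_seeds <- function() c(20L, 71L, 133L, 204L)

check_grid <- function(grid) {
  if (!is.numeric(grid) || !length(grid) || any(grid <= 0) ||
      any(diff(grid) >= 0)) {
    abort("epsilon grid must be strictly decreasing and positive.",
          class = "dpcc_parameter_error")
  }
  grid
}

#' Sweep the privacy parameter across seeds
#'
#' For every (epsilon, seed) cell, fits an epsilon-DP logistic regression and
#' extracts odds ratios; the non-private [fit_logistic()] fit on the same
#' covariates provides the reference estimates. Cell-level fit failures are
#' recorded (`failed = TRUE`) rather than aborting the sweep. When a ledger is
#' supplied, each cell release is charged `epsilon` against the budget.
#'
#' @param data a cohort data frame.
#' @param covariates model covariates; default: all binary and continuous.
#' @param grid strictly decreasing positive epsilons.
#' @param seeds integer vector of noise seeds (predetermined, not drawn).
#' @param data_norm,regularization forwarded to [dp_logistic_regression()].
#' @param ledger optional [privacy_ledger()].
#' @return a `sweep_result`: `estimates` tibble (`name`, `beta`, ..., `epsilon`,
#'   `seed`, `failed`), `reference` tibble, `grid`, `seeds`, `ledger`.
#' @export
epsilon_sweep <- function(data, covariates = NULL, grid = default_epsilon_grid(),
                          seeds = default_seeds(), data_norm = NULL,
                          regularization = NULL, ledger = NULL) {
  check_grid(grid)
  stopifnot(length(seeds) >= 1)
  ref_fit <- fit_logistic(data, covariates)
  reference <- odds_ratios(ref_fit)
  cells <- tidyr::expand_grid(epsilon = grid, seed = as.integer(seeds))
  est <- purrr::pmap(cells, function(epsilon, seed) {
    if (!is.null(ledger)) {
      ledger <<- privacy_accountant(
        ledger, paste0("sweep eps=", signif(epsilon, 4), " seed=", seed), epsilon)
    }
    tryCatch({
      fit <- dp_logistic_regression(
        data,
        privacy_params(epsilon, data_norm = data_norm,
                       regularization = regularization, seed = seed),
        covariates)
      out <- odds_ratios(fit)
      out$failed <- FALSE
      out
    }, error = function(e) {
      tibble::tibble(name = reference$name, beta = NA_real_, se = NA_real_,
                     or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_, epsilon = epsilon, seed = seed,
                     ci_basis = NA_character_, failed = TRUE)
    })
  })
  structure(
    list(estimates = dplyr::bind_rows(est), reference = reference,
         grid = grid, seeds = as.integer(seeds), ledger = ledger),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Epsilon sweep:", length(unique(x$reference$name)), "covariates x",
      length(x$grid), "epsilons x", length(x$seeds), "seeds\n")
  invisible(x)
}

#' Divergence epsilon: where private odds ratios leave the reference interval
#'
#' Divergence is operationalized as the DP odds-ratio point estimate falling
#' outside the non-private reference 95% CI. Scanning the grid in descending
#' order, the per-seed divergence onset is the largest grid epsilon at which
#' the DP OR lies outside the interval; transient re-entries at smaller
#' epsilons do not reset the onset. Across seeds, the range is
#' `[range_high, range_low] = [max, min]` of the onsets and `range_width` their
#' difference.
#'
#' @param sweep a [epsilon_sweep()] result.
#' @param covariate optional single covariate name; default: all.
#' @return a `divergence_summary` tibble: `name`, `n_seeds`,
#'   `n_seeds_diverged`, `range_low`, `range_high`, `range_width`,
#'   `onsets` (list column of per-seed onsets, `NA` = never diverged).
#' @export
divergence_epsilon <- function(sweep, covariate = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!is.null(covariate) && !covariate %in% sweep$reference$name) {
    abort(paste0("unknown covariate: ", covariate), class = "dpcc_key_error")
  }
  ref <- dplyr::select(sweep$reference, "name",
                       ref_low = "ci_low", ref_high = "ci_high")
  est <- dplyr::inner_join(sweep$estimates, ref, by = "name")
  if (!is.null(covariate)) est <- est[est$name == covariate, ]
  est$diverged <- !est$failed & (est$or < est$ref_low | est$or > est$ref_high)
  onset_tbl <- est |>
    dplyr::group_by(.data$name, .data$seed) |>
    dplyr::summarise(
      onset = if (any(.data$diverged)) max(.data$epsilon[.data$diverged]) else NA_real_,
      .groups = "drop")
  out <- onset_tbl |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      n_seeds_diverged = sum(!is.na(.data$onset)),
      range_low = if (any(!is.na(.data$onset))) min(.data$onset, na.rm = TRUE) else NA_real_,
      range_high = if (any(!is.na(.data$onset))) max(.data$onset, na.rm = TRUE) else NA_real_,
      onsets = list(setNames(.data$onset, .data$seed)),
      .groups = "drop") |>
    dplyr::mutate(range_width = .data$range_high - .data$range_low)
  class(out) <- c("divergence_summary", class(out))
  out
}

#' Aggregate sweep estimates across seeds
#'
#' Averages (or takes the median of) the log odds ratios across seeds per
#' (covariate, epsilon), a mitigation for seed p-hacking. CI bounds are
#' aggregated by the same statistic, also on the log scale, and flagged
#' descriptive: they are not valid intervals for the aggregate.
#'
#' @param sweep a [epsilon_sweep()] result with at least 2 seed columns.
#' @param method `"mean"` or `"median"`.
#' @return tibble: `name`, `epsilon`, `beta`, `or`, `ci_low`, `ci_high`,
#'   `n_seeds`, `ci_basis = "descriptive"`.
#' @export
seed_aggregate <- function(sweep, method = c("mean", "median")) {
  stopifnot(inherits(sweep, "sweep_result"))
  method <- match.arg(method)
  if (length(sweep$seeds) < 2) {
    abort("seed aggregation needs at least 2 seeds.", class = "dpcc_usage_error")
  }
  agg <- if (method == "mean") base::mean else stats::median
  sweep$estimates |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$name, .data$epsilon) |>
    dplyr::summarise(
      beta = agg(.data$beta), ci_low = exp(agg(log(.data$ci_low))),
      ci_high = exp(agg(log(.data$ci_high))), n_seeds = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(or = exp(.data$beta), ci_basis = "descriptive") |>
    dplyr::select("name", "epsilon", "beta", "or", "ci_low", "ci_high",
                  "n_seeds", "ci_basis")
}

#' Exact SHAP attributions for a linear-logistic model
#'
#' For a linear model with independent features the Shapley attribution of
#' feature j for row i is `phi_ij = beta_j (x_ij - mean(x_j))` on the log-odds
#' scale, and the attributions sum per row to `logit_i - mean(logit)`.
#'
#' @param fit a [fit_logistic()] or [dp_logistic_regression()] result.
#' @param data the data the attributions are evaluated on (defaults to the
#'   fitting data for DP fits).
#' @return an n-by-d matrix of attributions with the baseline (mean log-odds)
#'   in attribute `"baseline"`.
#' @export
shap_linear <- function(fit, data = NULL) {
  if (inherits(fit, "dp_logit")) {
    beta <- fit$coefficients
    covs <- fit$covariates
  } else {
    beta <- coef(fit)
    covs <- fit$covariates
  }
  if (is.null(data)) {
    if (!inherits(fit, "dp_logit")) {
      abort("`data` is required for non-private fits.", class = "dpcc_usage_error")
    }
    X <- fit$X[, covs, drop = FALSE]
  } else {
    X <- as.matrix(dplyr::mutate(data[covs], dplyr::across(dplyr::everything(), as.numeric)))
  }
  b <- beta[covs]
  centered <- sweep(X, 2, colMeans(X))
  phi <- sweep(centered, 2, b, `*`)
  attr(phi, "baseline") <- unname(beta["(Intercept)"] + sum(colMeans(X) * b))
  phi
}

#' Global SHAP importance
#' @param phi an attribution matrix from [shap_linear()].
#' @return tibble `name`, `mean_abs_shap`, sorted decreasing.
#' @export
shap_importance <- function(phi) {
  tibble::tibble(name = colnames(phi), mean_abs_shap = colMeans(abs(phi))) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap))
}

#' Brier score (mean squared probability error)
#' @param probabilities predicted probabilities in `[0, 1]`.
#' @param outcome 0/1 outcomes of the same length.
#' @return scalar in `[0, 1]`; 0 is perfect.
#' @export
brier_score <- function(probabilities, outcome) {
  if (length(probabilities) != length(outcome)) {
    abort("probabilities and outcome lengths differ.", class = "dpcc_usage_error")
  }
  stopifnot(all(probabilities >= 0 & probabilities <= 1), all(outcome %in% c(0, 1)))
  base::mean((probabilities - outcome)^2)
}

#' ROC area under the curve (Mann-Whitney formulation)
#'
#' Probability that a random case is scored above a random control, with ties
#' counted one half — computed from mid-ranks, equivalent to the trapezoidal
#' area under the empirical ROC curve.
#'
#' @param scores numeric risk scores.
#' @param outcome 0/1 outcomes; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, outcome) {
  if (length(scores) != length(outcome)) {
    abort("scores and outcome lengths differ.", class = "dpcc_usage_error")
  }
  stopifnot(all(outcome %in% c(0, 1)))
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present to compute the AUC.",
          class = "dpcc_usage_error")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Export a sweep (and divergence summary) as tidy files
#'
#' Writes `sweep_estimates.csv` (covariate, epsilon, seed, OR, CI, diverged
#' flag), `sweep_reference.csv`, and — when a divergence summary is given —
#' `divergence_summary.csv` plus a JSON digest. [read_sweep()] reconstructs the
#' sweep from a directory.
#'
#' @param sweep a [epsilon_sweep()] result.
#' @param path output directory (created if needed).
#' @param divergence optional [divergence_epsilon()] summary.
#' @return the directory path, invisibly.
#' @export
forest_export <- function(sweep, path, divergence = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", path), class = "dpcc_io_error")
  }
  ref <- dplyr::select(sweep$reference, "name", ref_low = "ci_low", ref_high = "ci_high")
  est <- dplyr::inner_join(sweep$estimates, ref, by = "name") |>
    dplyr::mutate(diverged = !.data$failed &
                    (.data$or < .data$ref_low | .data$or > .data$ref_high)) |>
    dplyr::select("name", "epsilon", "seed", "beta", "se", "or",
                  "ci_low", "ci_high", "p", "failed", "diverged")
  readr::write_csv(est, file.path(path, "sweep_estimates.csv"))
  readr::write_csv(sweep$reference, file.path(path, "sweep_reference.csv"))
  if (!is.null(divergence)) {
    readr::write_csv(dplyr::select(divergence, -"onsets"),
                     file.path(path, "divergence_summary.csv"))
    jsonlite::write_json(
      list(grid = sweep$grid, seeds = sweep$seeds,
           divergence = lapply(seq_len(nrow(divergence)), function(i) {
             list(name = divergence$name[i],
                  range_low = divergence$range_low[i],
                  range_high = divergence$range_high[i],
                  range_width = divergence$range_width[i],
                  onsets = as.list(divergence$onsets[[i]]))
           })),
      file.path(path, "divergence_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(list(grid = sweep$grid, seeds = sweep$seeds),
                       file.path(path, "sweep_meta.json"), digits = NA)
  invisible(path)
}

#' @rdname forest_export
#' @export
read_sweep <- function(path) {
  est <- readr::read_csv(file.path(path, "sweep_estimates.csv"),
                         show_col_types = FALSE, progress = FALSE)
  ref <- readr::read_csv(file.path(path, "sweep_reference.csv"),
                         show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(path, "sweep_meta.json"), simplifyVector = TRUE)
  structure(
    list(estimates = dplyr::select(est, -"diverged"),
         reference = ref, grid = meta$grid, seeds = as.integer(meta$seeds),
         ledger = NULL),
    class = "sweep_result"
  )
}

#' Model performance across the epsilon grid
#'
#' Brier score and ROC AUC of the DP model per (epsilon, seed), with the
#' non-private reference in the first rows (`epsilon = Inf`). The Brier score
#' is prevalence-sensitive and should only be compared across epsilons within
#' the same analysis, never across designs with different case fractions.
#'
#' @inheritParams epsilon_sweep
#' @return tibble: `epsilon`, `seed`, `brier`, `auc`.
#' @export
performance_sweep <- function(data, covariates = NULL, grid = default_epsilon_grid(),
                              seeds = default_seeds(), data_norm = NULL,
                              regularization = NULL) {
  check_grid(grid)
  ref <- fit_logistic(data, covariates)
  y <- as.numeric(data$case)
  rows <- list(tibble::tibble(epsilon = Inf, seed = NA_integer_,
                              brier = brier_score(ref$fitted.values, y),
                              auc = roc_auc(ref$fitted.values, y)))
  cells <- tidyr::expand_grid(epsilon = grid, seed = as.integer(seeds))
  dp_rows <- purrr::pmap(cells, function(epsilon, seed) {
    fit <- dp_logistic_regression(
      data, privacy_params(epsilon, data_norm = data_norm,
                           regularization = regularization, seed = seed),
      covariates)
    p <- plogis(drop(fit$X %*% fit$coefficients))
    tibble::tibble(epsilon = epsilon, seed = seed,
                   brier = brier_score(p, y), auc = roc_auc(p, y))
  })
  dplyr::bind_rows(c(rows, dp_rows))
}
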