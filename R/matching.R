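#' Propensity scores from baseline covariates
#'
#' Fitted probability of case membership from a logistic regression of case
#' status on exactly the listed baseline covariates (default: the package's
#' standard set — sex, ethnicity, COPD, 1-year exacerbation and OCS history,
#' smoking indicators, normalized age and asthma duration).
#'
#' @param data a cohort data frame.
#' @param covariates baseline covariate columns.
#' @return numeric vector of scores in (0, 1), one per row.
#' @export
propensity_scores <- function(data, covariates = propensity_covariates()) {
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    abort(paste0("baseline covariates missing from data: ",
                 paste(missing, collapse = ", ")), class = "dpcc_config_error")
  }
  fit <- fit_logistic(data, covariates)
  unname(fit$fitted.values)
}

#' Differentially private propensity scores
#'
#' As [propensity_scores()] but with the score model fitted by
#' [dp_logistic_regression()]; when a ledger is supplied the release is
#' recorded against the budget.
#'
#' @inheritParams propensity_scores
#' @param params a [privacy_params()].
#' @param ledger optional [privacy_ledger()]; pass via
#'   `dp_propensity_scores(...)$ledger` to retrieve the updated ledger.
#' @return a list: `scores` (in (0, 1)), `fit` (the `dp_logit`), `ledger`
#'   (updated, or `NULL`).
#' @export
dp_propensity_scores <- function(data, params, covariates = propensity_covariates(),
                                 ledger = NULL) {
  missing <- setdiff(covariates, names(data))
  if (length(missing)) {
    abort(paste0("baseline covariates missing from data: ",
                 paste(missing, collapse = ", ")), class = "dpcc_config_error")
  }
  fit <- dp_logistic_regression(data, params, covariates)
  if (!is.null(ledger)) {
    ledger <- privacy_accountant(ledger, "propensity_scores", params$epsilon)
  }
  scores <- plogis(drop(fit$X %*% fit$coefficients))
  list(scores = scores, fit = fit, ledger = ledger)
}

#' Greedy nearest-neighbor matching without replacement under a caliper
#'
#' Cases are processed in a seed-shuffled random order; each case receives up
#' to `ratio` nearest unused controls whose propensity score lies within
#' `caliper` of the case's score (nearest first; ties between equidistant
#' controls broken by the lower control row index). Controls are never reused.
#' Cases with no in-caliper control are reported unmatched; partial matches
#' (fewer than `ratio` controls) are kept. Deterministic given `seed`.
#'
#' @param scores numeric propensity scores, one per row.
#' @param outcome 0/1 case indicator aligned with `scores`.
#' @param ratio controls per case, >= 1.
#' @param caliper maximum |score difference| for a valid match, > 0. The
#'   caliper is on the raw propensity scale; set `logit_scale = TRUE` to match
#'   on the logit of the score instead.
#' @param seed integer seed for the case processing order.
#' @param logit_scale interpret `caliper` on the logit scale.
#' @return a `match_result`: `pairs` tibble (`case_id`, `control_id`,
#'   `score_case`, `score_control`, `distance`), `unmatched_cases`, `ratio`,
#'   `caliper`, `scores`.
#' @export
knn_match <- function(scores, outcome, ratio = 1L, caliper = 0.1, seed = 1L,
                      logit_scale = FALSE) {
  stopifnot(length(scores) == length(outcome), all(is.finite(scores)))
  check_positive(caliper, "caliper")
  if (ratio < 1 || ratio != round(ratio)) {
    abort("`ratio` must be a positive integer.", class = "dpcc_parameter_error")
  }
  s <- if (logit_scale) stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12)) else scores
  case_idx <- which(outcome == 1)
  ctrl_idx <- which(outcome == 0)
  if (!length(ctrl_idx)) {
    abort("no controls available to match.", class = "dpcc_usage_error")
  }
  order_cases <- withr::with_seed(as.integer(seed), sample(case_idx))
  cs <- s[ctrl_idx]
  o <- order(cs, ctrl_idx) # by score, ties by original row index
  cs_sorted <- cs[o]
  ctrl_sorted <- ctrl_idx[o]
  K <- length(ctrl_sorted)
  # equal-score runs, for exact lowest-index tie-breaking within a run
  run_id <- cumsum(c(TRUE, diff(cs_sorted) != 0))
  run_start <- which(c(TRUE, diff(run_id) != 0))
  run_end <- c(run_start[-1] - 1L, K)
  used <- logical(K)
  # pick the unused control with the lowest original row index in the
  # equal-score run containing sorted position j
  pick_in_run <- function(j) {
    a <- run_start[run_id[j]]; bnd <- run_end[run_id[j]]
    cand <- a:bnd
    cand <- cand[!used[cand]]
    cand[which.min(ctrl_sorted[cand])]
  }
  res_case <- vector("list", length(order_cases))
  unmatched <- integer()
  for (k in seq_along(order_cases)) {
    i <- order_cases[k]
    si <- s[i]
    # expanding two-pointer search outward from the insertion point
    l <- findInterval(si, cs_sorted)
    r <- l + 1L
    take <- integer()
    repeat {
      while (l >= 1L && used[l]) l <- l - 1L
      while (r <= K && used[r]) r <- r + 1L
      dl <- if (l >= 1L) si - cs_sorted[l] else Inf
      dr <- if (r <= K) cs_sorted[r] - si else Inf
      if (min(dl, dr) > caliper || length(take) >= ratio) break
      if (dl < dr) {
        j <- pick_in_run(l)
        used[j] <- TRUE; take <- c(take, j)
      } else if (dr < dl) {
        j <- pick_in_run(r)
        used[j] <- TRUE; take <- c(take, j)
      } else { # equidistant across sides: lower original control index wins
        jl <- pick_in_run(l); jr <- pick_in_run(r)
        j <- if (ctrl_sorted[jl] < ctrl_sorted[jr]) jl else jr
        used[j] <- TRUE; take <- c(take, j)
      }
    }
    if (length(take)) {
      res_case[[k]] <- tibble::tibble(
        case_id = i, control_id = ctrl_sorted[take],
        score_case = scores[i], score_control = scores[ctrl_sorted[take]],
        distance = abs(cs_sorted[take] - si)
      )
    } else {
      unmatched <- c(unmatched, i)
    }
  }
  pairs <- dplyr::bind_rows(res_case)
  if (!nrow(pairs)) {
    pairs <- tibble::tibble(case_id = integer(), control_id = integer(),
                            score_case = numeric(), score_control = numeric(),
                            distance = numeric())
  }
  pairs <- dplyr::arrange(pairs, .data$case_id, .data$distance, .data$control_id)
  structure(
    list(pairs = pairs, unmatched_cases = sort(unmatched),
         ratio = as.integer(ratio), caliper = caliper, seed = as.integer(seed),
         logit_scale = logit_scale, scores = scores),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("1:", x$ratio, " caliper ", x$caliper, " matching: ",
      length(unique(x$pairs$case_id)), " cases matched to ",
      nrow(x$pairs), " controls; ", length(x$unmatched_cases),
      " cases unmatched\n", sep = "")
  invisible(x)
}

#' Rows of the matched subset
#'
#' @param data the cohort the match was computed on.
#' @param match a [knn_match()] result.
#' @return the matched cases and controls as one tibble (attributes preserved).
#' @export
matched_data <- function(data, match) {
  stopifnot(inherits(match, "match_result"))
  idx <- c(unique(match$pairs$case_id), match$pairs$control_id)
  out <- data[idx, , drop = FALSE]
  attr(out, "kinds") <- attr(data, "kinds")
  attr(out, "normalized") <- attr(data, "normalized")
  out
}

#' Standardized mean difference between two groups
#'
#' `(mean1 - mean0) / sqrt((var1 + var0) / 2)`; for binary covariates the
#' arm variance is `p (1 - p)`. An SMD below 0.1 conventionally indicates
#' adequate balance. Zero pooled variance with unequal means returns an
#' infinite sentinel.
#'
#' @param values numeric (or 0/1) covariate values.
#' @param group 0/1 group indicator (1 = cases).
#' @return a single SMD.
#' @export
smd <- function(values, group) {
  stopifnot(length(values) == length(group), all(group %in% c(0, 1)))
  if (!any(group == 1) || !any(group == 0)) {
    abort("both groups must be non-empty.", class = "dpcc_usage_error")
  }
  x1 <- as.numeric(values[group == 1])
  x0 <- as.numeric(values[group == 0])
  binary <- all(c(x1, x0) %in% c(0, 1))
  v <- function(x) if (binary) base::mean(x) * (1 - base::mean(x)) else var(x)
  pooled <- (v(x1) + v(x0)) / 2
  diff_means <- base::mean(x1) - base::mean(x0)
  if (pooled == 0) {
    return(if (diff_means == 0) 0 else sign(diff_means) * Inf)
  }
  diff_means / sqrt(pooled)
}

#' Covariate balance before and after matching
#'
#' SMDs comparing all cases with all controls (`smd_before`) and matched cases
#' with matched controls (`smd_after`); the after column is only present when
#' a match result is supplied.
#'
#' @param data the cohort.
#' @param match optional [knn_match()] result.
#' @param covariates columns to report; default: all binary and continuous.
#' @return a `balance_table` tibble: `name`, `mean_cases`, `mean_controls`,
#'   `smd_before` (and `smd_after`).
#' @export
balance_table <- function(data, match = NULL, covariates = NULL) {
  check_cc_data(data)
  kinds <- covariate_kinds(data)
  covs <- covariates %||% names(kinds)[kinds %in% c("binary", "continuous")]
  y <- data$case
  out <- tibble::tibble(
    name = covs,
    mean_cases = vapply(covs, function(v) base::mean(as.numeric(data[[v]][y == 1])), numeric(1)),
    mean_controls = vapply(covs, function(v) base::mean(as.numeric(data[[v]][y == 0])), numeric(1)),
    smd_before = vapply(covs, function(v) smd(as.numeric(data[[v]]), y), numeric(1))
  )
  if (!is.null(match)) {
    stopifnot(inherits(match, "match_result"))
    mc <- unique(match$pairs$case_id)
    mk <- match$pairs$control_id
    out$smd_after <- vapply(covs, function(v) {
      smd(as.numeric(data[[v]][c(mc, mk)]), rep(c(1, 0), c(length(mc), length(mk))))
    }, numeric(1))
  }
  class(out) <- c("balance_table", class(out))
  out
}

#' Serialize a match result as a pair table
#' @param match a [knn_match()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_match <- function(match, path) {
  stopifnot(inherits(match, "match_result"))
  readr::write_csv(match$pairs, path)
  invisible(path)
}
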