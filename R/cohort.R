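#' Declare one covariate of a synthetic case-control cohort
#'
#' A covariate is described by its marginal distribution in each arm:
#' per-arm prevalences for binary covariates, per-arm means/SDs for continuous
#' ones, and per-arm level probabilities for categorical ones. A single-arm
#' form (`prev`, `mean`/`sd`, `probs`) is accepted for outcome-model cohorts
#' where case status is generated from the covariates rather than fixed by arm.
#'
#' @param name column name.
#' @param kind one of `"binary"`, `"continuous"`, `"categorical"`.
#' @param prev_cases,prev_controls binary prevalence per arm, in `[0, 1]`.
#' @param mean_cases,sd_cases,mean_controls,sd_controls continuous moments per
#'   arm; SDs must be non-negative.
#' @param levels character vector of categorical levels.
#' @param probs_cases,probs_controls per-arm level probabilities (sum to 1).
#' @param prev,mean,sd,probs single-arm shorthands, copied to both arms.
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(name, kind = c("binary", "continuous", "categorical"),
                           prev_cases = NULL, prev_controls = NULL,
                           mean_cases = NULL, sd_cases = NULL,
                           mean_controls = NULL, sd_controls = NULL,
                           levels = NULL, probs_cases = NULL, probs_controls = NULL,
                           prev = NULL, mean = NULL, sd = NULL, probs = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(prev)) prev_cases <- prev_controls <- prev
  if (!is.null(mean)) mean_cases <- mean_controls <- mean
  if (!is.null(sd)) sd_cases <- sd_controls <- sd
  if (!is.null(probs)) probs_cases <- probs_controls <- probs
  if (kind == "binary") {
    check_prob(prev_cases, paste0(name, ".prev_cases"))
    check_prob(prev_controls, paste0(name, ".prev_controls"))
  } else if (kind == "continuous") {
    stopifnot(is.numeric(mean_cases), is.numeric(mean_controls))
    if (sd_cases < 0 || sd_controls < 0) {
      abort(paste0("`", name, "`: sd must be >= 0."), class = "dpcc_spec_error")
    }
  } else {
    stopifnot(is.character(levels), length(levels) >= 2L)
    for (p in list(cases = probs_cases, controls = probs_controls)) {
      if (length(p) != length(levels) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
        abort(paste0("`", name, "`: level probabilities must be non-negative and sum to 1."),
              class = "dpcc_spec_error")
      }
    }
  }
  structure(
    list(name = name, kind = kind,
         prev_cases = prev_cases, prev_controls = prev_controls,
         mean_cases = mean_cases, sd_cases = sd_cases,
         mean_controls = mean_controls, sd_controls = sd_controls,
         levels = levels, probs_cases = probs_cases, probs_controls = probs_controls),
    class = "covariate_spec"
  )
}

#' Declare a synthetic case-control cohort
#'
#' @param n_cases,n_controls positive arm sizes.
#' @param covariates list of [covariate_spec()] objects with unique names.
#' @param seed default master seed used when [generate_cohort()] is called
#'   without one.
#' @param normalize should continuous columns be min-max normalized to `[0, 1]`
#'   (pooled over both arms)? Default `TRUE`, matching a DP pipeline where the
#'   row norm of the feature vector must be bounded.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases, n_controls, covariates, seed = 1L, normalize = TRUE) {
  check_positive(n_cases, "n_cases"); check_positive(n_controls, "n_controls")
  stopifnot(n_cases == round(n_cases), n_controls == round(n_controls))
  stopifnot(is.list(covariates), length(covariates) >= 1L)
  ok <- vapply(covariates, inherits, logical(1), "covariate_spec")
  if (!all(ok)) abort("all covariates must be covariate_spec objects.", class = "dpcc_spec_error")
  nms <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate covariate name: ", nms[duplicated(nms)][1]),
          class = "dpcc_spec_error")
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         covariates = setNames(covariates, nms), seed = as.integer(seed),
         normalize = isTRUE(normalize)),
    class = "cohort_spec"
  )
}

#' Default cohort specification: the published asthma case-control margins
#'
#' Returns the cohort specification used as the package's standard fixture:
#' 2714 cases with a 1-year asthma exacerbation and 19451 controls, with the
#' per-arm covariate margins of the source cohort's descriptive table —
#' dichotomized risk factors (age >= 60, female sex, non-White ethnicity,
#' anxiety, BMI >= 30, CKD, COPD, CVD, diabetes, hypertension, any cardinal
#' symptom, 1-year exacerbation history, 1-year OCS prescription), a smoking
#' category, a death indicator, and continuous age and asthma duration.
#'
#' Two descriptive-table inconsistencies are resolved as follows: the CKD
#' control prevalence uses the printed percentage (0.69%; the printed count is
#' inconsistent with the cohort margin), and BMI >= 30 in controls uses the
#' printed count 5735 (the printed percentage is inconsistent with the count).
#' Smoking level probabilities use the printed percentages, which sum to 100.00
#' in both arms, rather than the (internally inconsistent) counts.
#'
#' @return a [cohort_spec()] with `n_cases = 2714`, `n_controls = 19451`.
#' @export
table1_default_spec <- function() {
  b <- function(name, pc, pk) covariate_spec(name, "binary", prev_cases = pc, prev_controls = pk)
  cohort_spec(
    n_cases = 2714L, n_controls = 19451L, seed = 1L,
    covariates = list(
      b("age60", (1411 + 68) / 2714, (7823 + 398) / 19451),
      b("female", 0.6407, 0.5818),
      b("nonwhite", 0.0582, 0.0544),
      b("anxiety", 0.1352, 0.1128),
      b("bmi30", 0.3813, 5735 / 19451),
      b("ckd", 0.0125, 0.0069),
      b("copd", 0.1485, 0.0443),
      b("cvd", 0.0770, 0.0543),
      b("diabetes", 0.0203, 0.0196),
      b("hypertension", 0.2520, 0.1792),
      b("cardinal_symptoms", 0.8817, 0.6872),
      b("exacerbation_1y", 0.0644, 0.0112),
      b("ocs_rx_1y", 0.0589, 0.0218),
      covariate_spec("smoking", "categorical",
                     levels = c("non", "current", "previous"),
                     probs_cases = c(0.4997, 0.1206, 0.3797),
                     probs_controls = c(0.5591, 0.0934, 0.3475)),
      b("death", 0.0036, 0.0016),
      covariate_spec("age", "continuous",
                     mean_cases = 58.65, sd_cases = 7.84,
                     mean_controls = 56.47, sd_controls = 8.25),
      covariate_spec("asthma_duration", "continuous",
                     mean_cases = 15.37, sd_cases = 13.00,
                     mean_controls = 15.38, sd_controls = 12.74)
    )
  )
}

#' Covariates of the adjusted (fully dichotomized) risk-factor model
#' @return character vector of the 13 binary risk-factor columns.
#' @export
adjusted_covariates <- function() {
  c("age60", "female", "nonwhite", "anxiety", "bmi30", "ckd", "copd", "cvd",
    "diabetes", "hypertension", "cardinal_symptoms", "exacerbation_1y", "ocs_rx_1y")
}

#' Baseline covariates entering the propensity-score model
#'
#' Sex, ethnicity, COPD, 1-year exacerbation and OCS prescription history,
#' smoking status (two indicator columns) and normalized age and asthma
#' duration.
#' @return character vector of column names.
#' @export
propensity_covariates <- function() {
  c("female", "nonwhite", "copd", "exacerbation_1y", "ocs_rx_1y",
    "smoking_current", "smoking_previous", "age", "asthma_duration")
}

new_cc_data <- function(tbl, kinds, normalized) {
  out <- tibble::as_tibble(tbl)
  attr(out, "kinds") <- kinds
  attr(out, "normalized") <- normalized
  class(out) <- c("cc_data", class(out))
  out
}

draw_covariate <- function(cv, n, arm) {
  suffix <- if (arm == "case") "_cases" else "_controls"
  switch(cv$kind,
    binary = rbinom(n, 1L, cv[[paste0("prev", suffix)]]),
    continuous = rnorm(n, cv[[paste0("mean", suffix)]], cv[[paste0("sd", suffix)]]),
    categorical = factor(sample(cv$levels, n, replace = TRUE,
                                prob = cv[[paste0("probs", suffix)]]),
                         levels = cv$levels)
  )
}

#' Generate a synthetic case-control cohort
#'
#' Draws covariates independently within arm from the per-arm marginals in
#' `spec`: Bernoulli for binary, Normal for continuous, categorical sampling
#' for factors. Continuous columns are then min-max normalized to `[0, 1]`
#' using pooled (cases + controls) bounds when `spec$normalize` is set.
#' Identical `(spec, seed)` pairs yield bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a tibble with a 0/1 `case` column (cases first) and one column per
#'   covariate; covariate kind tags are carried in the `"kinds"` attribute and
#'   the `"normalized"` attribute records whether min-max scaling was applied.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec.", class = "dpcc_spec_error")
  }
  n1 <- spec$n_cases; n0 <- spec$n_controls
  withr::with_seed(as.integer(seed), {
    cols <- lapply(spec$covariates, function(cv) {
      c_case <- draw_covariate(cv, n1, "case")
      c_ctrl <- draw_covariate(cv, n0, "control")
      if (cv$kind == "categorical") {
        factor(c(as.character(c_case), as.character(c_ctrl)), levels = cv$levels)
      } else {
        c(c_case, c_ctrl)
      }
    })
  })
  tbl <- tibble::as_tibble(c(list(case = rep(c(1L, 0L), c(n1, n0))), cols))
  kinds <- vapply(spec$covariates, `[[`, character(1), "kind")
  if (spec$normalize) {
    for (nm in names(kinds)[kinds == "continuous"]) {
      x <- tbl[[nm]]
      rng <- range(x)
      tbl[[nm]] <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else rep(0, length(x))
    }
  }
  new_cc_data(tbl, kinds, normalized = spec$normalize)
}

#' Declare an outcome-model cohort for parameter-recovery studies
#'
#' Instead of fixing arm sizes, covariates are drawn from single-arm marginals
#' and the outcome from `Bernoulli(plogis(intercept + X beta))`, so the true
#' log-odds coefficients are known and can be compared with fitted ones.
#'
#' @param intercept log-odds intercept.
#' @param coefficients named numeric vector of log-odds coefficients; every
#'   name must match a covariate.
#' @param n number of rows.
#' @param covariates list of single-arm [covariate_spec()] objects.
#' @param seed default seed.
#' @return an `outcome_model_spec` list.
#' @export
outcome_model_spec <- function(intercept, coefficients, n, covariates, seed = 1L) {
  check_positive(n, "n")
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  nms <- vapply(covariates, `[[`, character(1), "name")
  if (!all(names(coefficients) %in% nms)) {
    missing <- setdiff(names(coefficients), nms)
    abort(paste0("coefficient names not among covariates: ",
                 paste(missing, collapse = ", ")), class = "dpcc_spec_error")
  }
  structure(
    list(intercept = intercept, coefficients = coefficients, n = as.integer(n),
         covariates = setNames(covariates, nms), seed = as.integer(seed)),
    class = "outcome_model_spec"
  )
}

#' Generate a cohort with known outcome-model coefficients
#'
#' @param spec an [outcome_model_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return a tibble as in [generate_cohort()]; the generating truth is attached
#'   as attributes `"true_intercept"` and `"true_coefficients"`.
#' @export
generate_outcome_cohort <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "outcome_model_spec")) {
    abort("`spec` must be an outcome_model_spec.", class = "dpcc_spec_error")
  }
  n <- spec$n
  withr::with_seed(as.integer(seed), {
    cols <- lapply(spec$covariates, draw_covariate, n = n, arm = "case")
    eta <- rep(spec$intercept, n)
    for (nm in names(spec$coefficients)) {
      eta <- eta + spec$coefficients[[nm]] * as.numeric(cols[[nm]])
    }
    y <- rbinom(n, 1L, plogis(eta))
  })
  tbl <- tibble::as_tibble(c(list(case = y), cols))
  kinds <- vapply(spec$covariates, `[[`, character(1), "kind")
  out <- new_cc_data(tbl, kinds, normalized = FALSE)
  attr(out, "true_intercept") <- spec$intercept
  attr(out, "true_coefficients") <- spec$coefficients
  out
}

#' Read and write cohort tables
#'
#' Cohorts are exchanged as delimited text with a header row; the outcome
#' column is named `case` with values 0/1.
#'
#' @param data a cohort tibble.
#' @param path file path (`.csv` or `.tsv`).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns a
#'   cohort tibble with inferred kind tags.
#' @export
write_cohort <- function(data, path) {
  check_cc_data(data)
  if (grepl("\\.tsv$", path)) readr::write_tsv(data, path) else readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tbl <- if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  check_cc_data(tbl)
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.character), factor))
  kinds <- covariate_kinds(tbl)
  cont <- names(kinds)[kinds == "continuous"]
  normalized <- length(cont) == 0 ||
    all(vapply(tbl[cont], function(x) min(x) >= 0 && max(x) <= 1, logical(1)))
  new_cc_data(tbl, kinds, normalized = normalized)
}

#' Serialize a cohort specification to YAML or JSON
#'
#' Keys mirror the [cohort_spec()]/[covariate_spec()] field names exactly.
#'
#' @param spec a [cohort_spec()].
#' @param path destination ending in `.yaml`/`.yml` or `.json`.
#' @return `write_cohort_spec()` returns `path` invisibly; `read_cohort_spec()`
#'   the reconstructed [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  raw <- list(
    n_cases = spec$n_cases, n_controls = spec$n_controls, seed = spec$seed,
    normalize = spec$normalize,
    covariates = lapply(unname(spec$covariates), function(cv) {
      Filter(Negate(is.null), unclass(cv))
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(raw, path)
  } else {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  covs <- lapply(raw$covariates, function(cv) {
    cv$probs_cases <- unlist(cv$probs_cases)
    cv$probs_controls <- unlist(cv$probs_controls)
    cv$levels <- unlist(cv$levels)
    do.call(covariate_spec, cv)
  })
  cohort_spec(raw$n_cases, raw$n_controls, covs,
              seed = raw$seed %||% 1L, normalize = raw$normalize %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
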