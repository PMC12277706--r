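#' @importFrom rlang abort warn .data
#' @importFrom stats qnorm pnorm plogis rbinom rnorm rgamma runif var coef vcov
#' @importFrom stats binomial glm model.matrix optim setNames rexp quantile median
#' @importFrom utils head
NULL

WALD_Z <- 1.959964

#' Derive a reproducible sub-stream seed
#'
#' One master seed spawns per-stage seeds so that pipeline stages draw from
#' independent, reproducible streams. All arithmetic stays below 2^31.
#'
#' @param seed master seed (integer-like).
#' @param stage character label of the stage.
#' @param index optional integer offset (e.g. replicate number).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; exact in doubles
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% m
  s <- (abs(seed) %% m)
  s <- (s * 48271) %% m
  s <- (s + h * 7919 + as.numeric(index) * 104729) %% m
  as.integer(s %% (m - 2) + 1)
}

# scalar checks ---------------------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number."),
          class = "dpcc_parameter_error")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(paste0("`", name, "` must lie in [0, 1]."),
          class = "dpcc_spec_error")
  }
  invisible(x)
}

# dataset helpers -------------------------------------------------------

#' Identify the outcome column and covariate kinds of a cohort table
#'
#' Cohort tables carry their covariate kind tags ("binary"/"continuous"/
#' "categorical") as an attribute when produced by [generate_cohort()]; for
#' plain data frames kinds are inferred (0/1 columns are binary, factors and
#' characters categorical, the rest continuous).
#'
#' @param data a data frame with a 0/1 `case` column.
#' @return named character vector of kinds, one per covariate column.
#' @export
covariate_kinds <- function(data) {
  stopifnot(is.data.frame(data))
  kinds <- attr(data, "kinds")
  covs <- setdiff(names(data), "case")
  if (!is.null(kinds) && all(covs %in% names(kinds))) {
    return(kinds[covs])
  }
  vapply(data[covs], function(x) {
    if (is.factor(x) || is.character(x)) return("categorical")
    ux <- unique(x[!is.na(x)])
    if (all(ux %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
}

check_cc_data <- function(data, require_case = TRUE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "dpcc_usage_error")
  }
  if (require_case) {
    if (!"case" %in% names(data)) {
      abort("`data` must contain a 0/1 outcome column named `case`.",
            class = "dpcc_usage_error")
    }
    y <- data$case
    if (!all(y %in% c(0, 1))) {
      abort("`case` must contain only 0 and 1.", class = "dpcc_usage_error")
    }
    if (sum(y == 1) < 1 || sum(y == 0) < 1) {
      abort("`data` needs at least one case and one control.",
            class = "dpcc_usage_error")
    }
  }
  if (anyNA(data)) {
    abort("`data` must not contain missing values (complete-case analysis).",
          class = "dpcc_usage_error")
  }
  invisible(data)
}

# numerically stable log(1 + exp(t))
log1pexp <- function(t) {
  pmax(t, 0) + log1p(exp(-abs(t)))
}
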