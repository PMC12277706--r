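#' Configure an end-to-end DP case-control run
#'
#' Bundles every knob of the pipeline. Each stochastic stage derives its own
#' sub-seed from the single master `seed` via [derive_seed()]; no randomness is
#' left implicit.
#'
#' @param cohort a [cohort_spec()] (simulated input) or a path to a delimited
#'   cohort table with a 0/1 `case` column.
#' @param grid strictly decreasing positive epsilon grid.
#' @param seeds predetermined DP noise seeds.
#' @param seed master seed for cohort generation and matching order.
#' @param budget total privacy budget (used when `accounting = TRUE`).
#' @param accounting charge sweep releases against the budget?
#' @param trust_model `"sde"` (researchers inside a secure data environment:
#'   only final released outputs are charged) or `"remote_query"` (every
#'   released intermediate is charged: a noisy descriptive table is produced
#'   with `epsilon_descriptives` per covariate and charged too).
#' @param epsilon_descriptives per-count epsilon of the remote-query noisy
#'   descriptives.
#' @param ratio controls per case in matching.
#' @param caliper propensity-score caliper.
#' @param dp_propensity apply DP to the propensity model (epsilon
#'   `epsilon_propensity`, charged when accounting).
#' @param epsilon_propensity epsilon of the DP propensity release.
#' @param exclude_deaths drop participants with `death == 1` before analysis.
#' @param unadjusted_contingency also produce unadjusted contingency-table ORs
#'   per adjusted covariate.
#' @param constant_se_pr_ci use the constant log-SE prevalence-ratio interval.
#' @param adjusted_covariates,propensity_covariates model column sets.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = table1_default_spec(),
                       grid = default_epsilon_grid(),
                       seeds = default_seeds(),
                       seed = 1L,
                       budget = NULL,
                       accounting = FALSE,
                       trust_model = c("sde", "remote_query"),
                       epsilon_descriptives = 0.1,
                       ratio = 1L,
                       caliper = 0.1,
                       dp_propensity = FALSE,
                       epsilon_propensity = 1,
                       exclude_deaths = FALSE,
                       unadjusted_contingency = FALSE,
                       constant_se_pr_ci = FALSE,
                       adjusted_covariates = dpcc::adjusted_covariates(),
                       propensity_covariates = dpcc::propensity_covariates()) {
  trust_model <- match.arg(trust_model)
  check_grid(grid)
  if (accounting) check_positive(budget, "budget")
  structure(
    list(cohort = cohort, grid = grid, seeds = as.integer(seeds),
         seed = as.integer(seed), budget = budget, accounting = accounting,
         trust_model = trust_model, epsilon_descriptives = epsilon_descriptives,
         ratio = as.integer(ratio), caliper = caliper,
         dp_propensity = dp_propensity, epsilon_propensity = epsilon_propensity,
         exclude_deaths = exclude_deaths,
         unadjusted_contingency = unadjusted_contingency,
         constant_se_pr_ci = constant_se_pr_ci,
         adjusted_covariates = adjusted_covariates,
         propensity_covariates = propensity_covariates),
    class = "run_config"
  )
}

#' Read or write a run configuration (YAML or JSON)
#' @param config a [run_config()].
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   the reconstructed config.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- unclass(config)
  if (inherits(raw$cohort, "cohort_spec")) {
    spec_path <- sub("(\\.[a-z]+)$", "_cohort\\1", path)
    write_cohort_spec(raw$cohort, spec_path)
    raw$cohort <- basename(spec_path)
    raw$cohort_is_spec <- TRUE
  }
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(raw, path)
  else jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (isTRUE(raw$cohort_is_spec)) {
    raw$cohort <- read_cohort_spec(file.path(dirname(path), raw$cohort))
  }
  raw$cohort_is_spec <- NULL
  raw$grid <- unlist(raw$grid)
  raw$seeds <- unlist(raw$seeds)
  raw$adjusted_covariates <- unlist(raw$adjusted_covariates)
  raw$propensity_covariates <- unlist(raw$propensity_covariates)
  do.call(run_config, raw)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the full simulate-fit-match-sweep-report pipeline
#'
#' Executes every stage on one cohort and writes all artifacts to `out_dir`:
#' effect tables (adjusted and matched), prevalence ratios, balance table,
#' sweep estimates with divergence summary, performance metrics, the privacy
#' ledger, and a manifest (config hash, package version, seeds). Identical
#' configs produce identical artifacts. Stage errors abort with the failing
#' stage named.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`data`, `adjusted`,
#'   `match`, `balance`, `sweep`, `divergence`, `performance`, `ledger`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", label, "' failed: ", conditionMessage(e)),
            class = c("dpcc_stage_error", class(e)[1]), parent = e)
    })
  }
  ledger <- if (config$accounting) privacy_ledger(config$budget) else NULL

  # -- simulate / load ----------------------------------------------------
  data <- stage("simulate", {
    if (inherits(config$cohort, "cohort_spec")) {
      generate_cohort(config$cohort, seed = derive_seed(config$seed, "simulate"))
    } else {
      read_cohort(config$cohort)
    }
  })
  if ("smoking" %in% names(data) && !is.numeric(data$smoking)) {
    data <- expand_smoking(data)
  }
  if (config$exclude_deaths && "death" %in% names(data)) {
    data <- dplyr::filter(data, .data$death == 0)
  }

  # -- descriptives -------------------------------------------------------
  covs <- config$adjusted_covariates
  desc <- stage("descriptives", {
    purrr::map_dfr(covs, function(v) {
      a <- sum(data[[v]][data$case == 1]); b <- sum(data[[v]][data$case == 0])
      pr <- prevalence_ratio(a, sum(data$case == 1), max(b, 1), sum(data$case == 0),
                             constant_se = config$constant_se_pr_ci)
      pr$name <- v
      pr
    })
  })
  if (config$accounting && config$trust_model == "remote_query") {
    noisy <- desc
    for (i in seq_len(nrow(desc))) {
      ledger <- privacy_accountant(ledger, paste0("descriptive count ", desc$name[i]),
                                   config$epsilon_descriptives)
      noisy$a[i] <- laplace_mechanism(desc$a[i], 1, config$epsilon_descriptives,
                                      seed = derive_seed(config$seed, "descriptives", i))
    }
    readr::write_csv(noisy, file.path(out_dir, "descriptives_dp.csv"))
  }
  readr::write_csv(desc, file.path(out_dir, "prevalence_ratios.csv"))

  # -- adjusted fit -------------------------------------------------------
  adjusted <- stage("fit", fit_logistic(data, covs))
  eff <- odds_ratios(adjusted)
  eff$epsilon <- NA_real_; eff$seed <- NA_integer_
  readr::write_csv(eff, file.path(out_dir, "effects_adjusted.csv"))

  if (config$unadjusted_contingency) {
    cont <- purrr::map_dfr(covs, function(v) {
      a <- sum(data[[v]] == 1 & data$case == 1); b <- sum(data[[v]] == 0 & data$case == 1)
      cc <- sum(data[[v]] == 1 & data$case == 0); d <- sum(data[[v]] == 0 & data$case == 0)
      out <- contingency_or(a, b, cc, d)
      out$name <- v
      out
    })
    readr::write_csv(cont, file.path(out_dir, "effects_contingency.csv"))
  }

  # -- matching -----------------------------------------------------------
  match_seed <- derive_seed(config$seed, "match")
  scores <- stage("match", {
    if (config$dp_propensity) {
      res <- dp_propensity_scores(
        data, privacy_params(config$epsilon_propensity,
                             seed = derive_seed(config$seed, "dp-propensity")),
        config$propensity_covariates, ledger = ledger)
      ledger <- res$ledger
      res$scores
    } else {
      propensity_scores(data, config$propensity_covariates)
    }
  })
  match <- stage("match", knn_match(scores, data$case, ratio = config$ratio,
                                    caliper = config$caliper, seed = match_seed))
  balance <- balance_table(data, match)
  readr::write_csv(balance, file.path(out_dir, "balance.csv"))
  write_match(match, file.path(out_dir, "matched_pairs.csv"))

  mdata <- matched_data(data, match)
  matched_fit <- stage("fit-matched", fit_logistic(mdata, covs))
  meff <- odds_ratios(matched_fit)
  meff$epsilon <- NA_real_; meff$seed <- NA_integer_
  readr::write_csv(meff, file.path(out_dir, "effects_matched.csv"))

  # -- sweep --------------------------------------------------------------
  sweep <- stage("sweep", epsilon_sweep(
    data, covs, grid = config$grid, seeds = config$seeds, ledger = ledger))
  if (!is.null(sweep$ledger)) ledger <- sweep$ledger
  divergence <- divergence_epsilon(sweep)
  forest_export(sweep, out_dir, divergence)

  perf <- stage("report", performance_sweep(
    data, covs, grid = config$grid, seeds = config$seeds))
  readr::write_csv(perf, file.path(out_dir, "performance.csv"))

  if (!is.null(ledger)) write_ledger(ledger, file.path(out_dir, "ledger.json"))

  manifest <- list(
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("dpcc")),
    seed = config$seed, seeds = config$seeds, grid = config$grid,
    n = nrow(data), n_cases = sum(data$case == 1),
    trust_model = config$trust_model,
    artifacts = sort(list.files(out_dir))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = data, adjusted = adjusted, match = match,
                 balance = balance, sweep = sweep, divergence = divergence,
                 performance = perf, ledger = ledger, manifest = manifest))
}
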