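#' Forest plot of private odds ratios across epsilon
#'
#' ORs and Wald CIs per epsilon (one panel per covariate, one colour per seed)
#' with the non-private reference estimate and its 95% CI as a shaded band.
#'
#' @param sweep a [epsilon_sweep()] result.
#' @param covariates subset of covariates to show; default: all.
#' @return a ggplot object.
#' @export
plot_forest <- function(sweep, covariates = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  est <- dplyr::filter(sweep$estimates, !.data$failed)
  ref <- sweep$reference
  if (!is.null(covariates)) {
    est <- est[est$name %in% covariates, ]
    ref <- ref[ref$name %in% covariates, ]
  }
  ggplot2::ggplot(est, ggplot2::aes(x = factor(signif(.data$epsilon, 3)),
                                    y = .data$or,
                                    colour = factor(.data$seed))) +
    ggplot2::geom_rect(data = ref, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf,
                                    ymin = .data$ci_low, ymax = .data$ci_high),
                       fill = "grey80", alpha = 0.5) +
    ggplot2::geom_hline(data = ref, ggplot2::aes(yintercept = .data$or),
                        linetype = 2, colour = "grey30") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.6),
                             size = 0.25) +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epsilon (descending privacy loss)", y = "odds ratio (log scale)",
                  colour = "seed") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sweep_result <- function(object, ...) plot_forest(object, ...)

#' Balance plot of standardized mean differences
#'
#' SMD per covariate before and, when available, after matching, with the
#' conventional 0.1 balance threshold.
#'
#' @param balance a [balance_table()].
#' @return a ggplot object.
#' @export
plot_balance <- function(balance) {
  stopifnot(inherits(balance, "balance_table"))
  long <- tidyr::pivot_longer(
    tibble::as_tibble(balance),
    dplyr::any_of(c("smd_before", "smd_after")),
    names_to = "stage", values_to = "smd", names_prefix = "smd_")
  long$stage <- factor(long$stage, levels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd),
                                     y = stats::reorder(.data$name, abs(.data$smd)),
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.balance_table <- function(object, ...) plot_balance(object, ...)

#' Calibration and discrimination across epsilon
#'
#' Brier score and ROC AUC per epsilon (mean across seeds) with the
#' non-private reference as a horizontal line.
#'
#' @param perf a [performance_sweep()] tibble.
#' @return a ggplot object.
#' @export
plot_performance <- function(perf) {
  ref <- perf[is.infinite(perf$epsilon), ]
  dp <- perf[is.finite(perf$epsilon), ] |>
    dplyr::group_by(.data$epsilon) |>
    dplyr::summarise(brier = base::mean(.data$brier), auc = base::mean(.data$auc),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("brier", "auc"), names_to = "metric")
  refl <- tidyr::pivot_longer(ref[c("brier", "auc")], dplyr::everything(),
                              names_to = "metric")
  ggplot2::ggplot(dp, ggplot2::aes(x = .data$epsilon, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(data = refl, ggplot2::aes(yintercept = .data$value),
                        linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epsilon (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
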