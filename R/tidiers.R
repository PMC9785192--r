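#' Tidy a simulation result
#'
#' @param x A `pbpk_result`.
#' @param ... Unused.
#' @return Tibble: compound, time_h, conc_ng_mL.
#' @export
tidy.pbpk_result <- function(x, ...) x$profiles

#' One-row summary of a simulation result
#'
#' @param x A `pbpk_result`.
#' @param ... Unused.
#' @return Tibble: one row per compound with NCA metrics over the whole
#'   horizon and the worst mass-balance residual.
#' @export
glance.pbpk_result <- function(x, ...) {
  purrr::map_dfr(unique(x$profiles$compound), function(cmp) {
    n <- nca(x, cmp)
    mbr <- max(x$mass_balance$residual[x$mass_balance$compound == cmp])
    dplyr::mutate(n, max_mass_balance_residual = mbr)
  })
}

#' @export
tidy.ddi_result <- function(x, ...) x$per_subject

#' @export
glance.ddi_result <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    victim = x$victim, perpetrator = x$perpetrator,
    n = nrow(x$per_subject),
    cmax_ratio = s$median[s$quantity == "cmax_ratio"],
    auc_last_ratio = s$median[s$quantity == "auc_last_ratio"],
    cmax_with = s$median[s$quantity == "cmax_with"],
    cmax_alone = s$median[s$quantity == "cmax_alone"],
    auc_with = s$median[s$quantity == "auc_with"],
    auc_alone = s$median[s$quantity == "auc_alone"])
}

#' @export
tidy.ki_estimate <- function(x, ...) x$trace

#' @export
glance.ki_estimate <- function(x, ...) {
  tibble::tibble(ki_hat = x$ki_hat, objective_value = x$objective_value,
                 start_value = x$start_value,
                 lower = x$bounds[1], upper = x$bounds[2],
                 converged = x$converged)
}

#' @export
tidy.sensitivity_result <- function(x, ...) x$scan

#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(s_auc = x$s_auc, s_cmax = x$s_cmax,
                 variation_range = x$variation_range, steps = x$steps)
}

#' Plot concentration-time profiles
#'
#' @param object A `pbpk_result`.
#' @param log_y Log10 concentration axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pbpk_result <- function(object, log_y = FALSE, ...) {
  p <- ggplot2::ggplot(object$profiles,
                       ggplot2::aes(x = .data$time_h, y = .data$conc_ng_mL,
                                    colour = .data$compound)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot per-subject DDI exposure ratios
#'
#' @param object A `ddi_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ddi_result <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$per_subject[, c("subject", "cmax_ratio", "auc_last_ratio")],
    -"subject", names_to = "metric", values_to = "ratio")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$ratio)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Exposure ratio (with / alone)") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity scan
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$scan[object$scan$ok, ],
                           c("auc", "cmax"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$multiplier, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Parameter multiplier", y = "Metric",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit scatter of predictions versus observations
#'
#' Pred-obs scatter with identity and 2-fold guide lines.
#'
#' @param data Tibble with `conc_pred` and `conc_obs`.
#' @return A ggplot.
#' @export
plot_goodness_of_fit <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$conc_obs,
                                     y = .data$conc_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(2),
                         linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = -log10(2),
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Observed (ng/mL)", y = "Predicted (ng/mL)") +
    ggplot2::theme_minimal()
}
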