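#' Plot a time-dependent ROC curve
#'
#' @param object a `td_roc`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.td_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fp, y = .data$tp)) +
    ggplot2::geom_path(colour = "#B2182B") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Time-dependent ROC at t* = %g (AUC = %.3f)",
                      object$t_star, object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot the AIC (or Youden) cut-off profile
#'
#' @param object a `risk_cutoff` from [aic_cutoff()].
#' @param ... unused.
#' @return A ggplot with the selected cut-off marked.
#' @export
autoplot.risk_cutoff <- function(object, ...) {
  ycol <- if (object$method == "aic") "aic" else "youden"
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$cutoff, y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "#B2182B",
                        linetype = "dashed") +
    ggplot2::labs(x = "Risk-score cut-off", y = toupper(ycol),
                  title = sprintf("Cut-off profile (c* = %.3g)",
                                  object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by risk group
#'
#' @param clinical tibble with `os_time`, `os_status`.
#' @param group factor of group labels aligned with `clinical` (e.g. the
#'   `risk_group` column produced by [apply_cutoff()]).
#' @return A ggplot of the product-limit step curves, annotated with the
#'   log-rank p-value.
#' @export
plot_km <- function(clinical, group) {
  group <- droplevels(as.factor(group))
  km <- purrr::map_dfr(levels(group), function(g) {
    sel <- group == g
    dplyr::mutate(km_estimate(clinical$os_time[sel], clinical$os_status[sel]),
                  group = g)
  })
  lr <- logrank_test(clinical$os_time, clinical$os_status, group)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL,
                  subtitle = sprintf("log-rank p = %.3g", lr$p)) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of Spearman correlations with immune features
#'
#' @param correlations tibble from [spearman_immune()].
#' @return A ggplot, features ordered by rho.
#' @export
plot_immune_correlation <- function(correlations) {
  df <- dplyr::filter(correlations, !is.na(.data$rho)) |>
    dplyr::mutate(label = paste(.data$cell_type, .data$method, sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho,
                                   y = stats::reorder(.data$label, .data$rho),
                                   colour = .data$method)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rho,
                                       yend = stats::reorder(.data$label,
                                                             .data$rho))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Spearman rho with risk score", y = NULL) +
    ggplot2::theme_minimal()
}
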