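#' Plot a Rescorla-Wagner trajectory
#'
#' Shows the per-trial predicted outcome with the contingency-space
#' outcomes overlaid as points.
#'
#' @param object A `blt_trajectory` from [rw_trajectory()] or
#'   [rw_dual_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blt_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$v), colour = "#2166ac") +
    ggplot2::geom_point(ggplot2::aes(y = .data$o), shape = 21,
                        fill = "grey80", size = 1.5) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Trial", y = "Predicted outcome v",
                  title = "Rescorla-Wagner prediction trajectory") +
    ggplot2::theme_minimal()
}

#' Plot parameter-recovery scatter
#'
#' Simulated against recovered learning rates, one panel per noise level
#' (and per parameter for dual-rate models), from a single representative
#' run, with the identity line and the per-noise Fisher-z mean
#' correlation in the panel label.
#'
#' @param object A `blt_recovery` from [recovery_experiment()].
#' @param run Which run to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blt_recovery <- function(object, run = 1L, ...) {
  draws <- dplyr::filter(object$draws, .data$run == !!run)
  lab <- object$summary |>
    dplyr::mutate(label = sprintf("noise = %g, %s (mean r = %.2f)",
                                  .data$noise, .data$parameter,
                                  .data$mean_r))
  draws <- dplyr::left_join(draws, lab[c("noise", "parameter", "label")],
                            by = c("noise", "parameter"))
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$simulated,
                                      y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, colour = "#2166ac") +
    ggplot2::facet_wrap(~label) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Simulated learning rate",
                  y = "Recovered learning rate",
                  title = paste("Parameter recovery:", object$model_id)) +
    ggplot2::theme_minimal()
}

#' Plot a Spearman correlation matrix as a heatmap
#'
#' @param object A `blt_corr_matrix` from [spearman_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blt_corr_matrix <- function(object, ...) {
  vars <- attr(object, "variables")
  df <- dplyr::mutate(as_tibble(object),
                      var1 = factor(.data$var1, levels = vars),
                      var2 = factor(.data$var2, levels = rev(vars)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 2.5, na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
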