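#' Plots of kinematic signals and analysis results
#'
#' @name plots
NULL

#' Plot helical angle and angular speed for one trial
#'
#' Two stacked panels (helical angle, 3-D angular speed) over time; if a
#' segment is supplied, dashed vertical lines mark the detected start and stop
#' of the movement.
#'
#' @param object A `kinematic_signals` object.
#' @param segment Optional `movement_segment` to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kinematic_signals
#' @export
autoplot.kinematic_signals <- function(object, segment = NULL, ...) {
  g <- object$grid |>
    tidyr::pivot_longer(c("helical_angle_deg", "angular_speed_deg_s"),
                        names_to = "signal", values_to = "value") |>
    dplyr::mutate(signal = factor(
      .data$signal, levels = c("helical_angle_deg", "angular_speed_deg_s"),
      labels = c("helical angle (deg)", "angular speed (deg/s)")
    ))
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1L, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = NULL,
      title = sprintf("subject %s, trial %d (%s rotation)",
                      object$subject_id, object$trial_index, object$direction)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(segment)) {
    marks <- object$grid$time_s[c(segment$start_idx, segment$stop_idx)]
    p <- p + ggplot2::geom_vline(xintercept = marks, linetype = "dashed")
  }
  p
}

#' VIP plot of an O-PLS model
#'
#' Predictors ordered by VIP with their jack-knife intervals; reference lines
#' at the influential (1) and unimportant (0.5) levels.
#'
#' @param object An `opls_model`.
#' @param top Show at most this many predictors.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot opls_model
#' @export
autoplot.opls_model <- function(object, top = 20, ...) {
  d <- tidy(object) |> dplyr::slice_head(n = top)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$predictor, .data$vip), y = .data$vip
  )) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$significant), show.legend = FALSE) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$vip_lo, ymax = .data$vip_hi), width = 0.3
    ) +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "VIP",
                  subtitle = sprintf("R2Y = %.3f, Q2 = %.3f", object$r2y, object$q2)) +
    ggplot2::theme_minimal()
}

#' Scatter of peak speed against the other kinematic variables by group
#'
#' @param subjects Subject-level metrics tibble with `group` and the kinematic
#'   variables.
#' @param x_var Variable on the x axis (default peak speed).
#' @param y_vars Variables plotted against it.
#' @return A ggplot object, one facet per variable.
#' @export
plot_group_scatter <- function(subjects, x_var = "peak_speed_deg_s",
                               y_vars = c("rom_deg", "npa", "ad_ratio",
                                          "sid_pct", "cm")) {
  d <- subjects |>
    tidyr::pivot_longer(dplyr::all_of(y_vars), names_to = "variable",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data[[x_var]], y = .data$value, colour = .data$group
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = x_var, y = NULL) +
    ggplot2::theme_minimal()
}
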