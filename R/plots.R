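# ggplot2 displays for the main result types.

#' Plot a signal tibble
#'
#' @param x Signal tibble (`time_s` plus one value column).
#' @param ylab Axis label.
#' @return A ggplot.
#' @export
plot_signal <- function(x, ylab = signal_value_col(x)) {
  col <- signal_value_col(x)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$time_s, y = .data[[col]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.reg_template <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$phase, y = .data$w)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "cycle phase", y = "impedance (ohm)",
                  title = sprintf("Standardized REG waveform (%d cycles, mean period %.2f s)",
                                  object$n_cycles, object$mean_period)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.recovery_curve <- function(object, theta = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle_time, y = .data$r)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "time (s)", y = "correlation with template") +
    ggplot2::coord_cartesian(ylim = c(min(object$r, 0.5), 1)) +
    ggplot2::theme_minimal()
  if (!is.null(theta)) p <- p + ggplot2::geom_hline(yintercept = theta, linetype = "dashed")
  p
}

#' @export
autoplot.lti_fit <- function(object, measured = NULL, fs = NULL, window_s = NULL, ...) {
  fs <- fs %||% object$fs
  n <- length(object$predicted)
  t <- (seq_len(n) - 1) / fs
  d <- tibble(time_s = t, series = "predicted", value = object$predicted)
  if (!is.null(measured)) {
    d <- dplyr::bind_rows(d, tibble(time_s = t, series = "measured",
                                    value = measured - mean(measured)))
  }
  if (!is.null(window_s)) d <- d[d$time_s >= window_s[1] & d$time_s <= window_s[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value, color = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "flow perturbation (ohm)",
                  title = sprintf("Free-run fit: tau = %.4g s, RMSE = %.3g, R2 = %.3f",
                                  object$tau, object$rmse, object$r2)) +
    ggplot2::theme_minimal()
}
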