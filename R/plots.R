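# ggplot2 visualisations for the main result types.

#' @export
autoplot.epsc_train <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ap_time_s,
                                       y = .data$amplitude_nA)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "AP time (s)", y = "EPSC amplitude (nA)",
                  title = sprintf("EPSC train (%s)", attr(object, "mode") %||% "")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.exp_fit <- function(object, n_curve = 200, ...) {
  d <- object$data
  grid <- tibble(interval_s = exp(seq(log(min(d$interval_s)),
                                      log(max(d$interval_s)),
                                      length.out = n_curve)))
  grid$value <- predict(object, grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval_s, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Recovery interval (s)", y = "Recovery",
                  title = sprintf("%s-exponential fit, tau_w = %.3g s",
                                  object$model, object$tau_w)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.recovery_dataset <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$interval_s, y = .data$frac_recovery)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Recovery interval (s)", y = "Fractional recovery") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mini_detection <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(x = .data$amplitude_nA)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "mEPSC amplitude (nA)", y = "Count",
                  title = sprintf("%d events, %.2g Hz",
                                  nrow(object$events), object$frequency_hz)) +
    ggplot2::theme_minimal()
}
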