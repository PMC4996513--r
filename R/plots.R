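# ggplot2 methods for the result objects.

#' Plot a cohort trace
#'
#' Stacked-area chart of state occupancy over the model horizon.
#'
#' @param object An `nbd_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nbd_trace
autoplot.nbd_trace <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(
      years = .data$cycle * object$settings$cycle_length,
      state = factor(.data$state, levels = nbd_states())
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$years, .data$occupancy, fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(
      x = "Years since model entry", y = "Cohort occupancy",
      title = paste("Cohort trace:", object$arm)
    )
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the PSA draws in incremental cost / incremental QALY space,
#' with the mean draw and willingness-to-pay reference lines.
#'
#' @param object An `nbd_psa`.
#' @param wtp Willingness-to-pay thresholds drawn as reference lines
#'   (GBP/QALY).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nbd_psa
autoplot.nbd_psa <- function(object, wtp = c(20000, 30000), ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$delta_qalys, .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::annotate("point",
      x = mean(pts$delta_qalys), y = mean(pts$delta_cost),
      colour = "red", size = 3
    ) +
    ggplot2::labs(
      x = "Incremental QALYs", y = "Incremental cost (GBP)",
      title = "Cost-effectiveness plane"
    )
  for (l in wtp) {
    p <- p + ggplot2::geom_abline(slope = l, intercept = 0, linetype = "dashed")
  }
  p
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param object An `nbd_ceac`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nbd_ceac
autoplot.nbd_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (GBP/QALY)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    )
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning the low/high result for the most influential
#' parameters, centred on the base-case result.
#'
#' @param object An `nbd_dsa`.
#' @param n_parameters Number of top-ranked parameters to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot nbd_dsa
autoplot.nbd_dsa <- function(object, n_parameters = 15, ...) {
  df <- utils::head(object, n_parameters) |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = rev(.data$parameter)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$result_low, xend = .data$result_high,
      y = .data$parameter, yend = .data$parameter
    ), linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = df$result_base[1], linetype = "dashed") +
    ggplot2::labs(
      x = "Incremental net monetary benefit (GBP)", y = NULL,
      title = "One-way sensitivity analysis"
    )
}
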