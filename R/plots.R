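#' Plot a scan profile
#'
#' @param object A `sweep_scan` from [clr_scan()] or [omega_max_scan()].
#' @param threshold Optional [calibrate_threshold()] result drawn as a
#'   horizontal cutoff line.
#' @param x_sel Optional selected-site position drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_scan <- function(object, threshold = NULL, x_sel = NULL, ...) {
  df <- tidy(object)
  ylab <- if (object$statistic_name == "clr") {
    "composite likelihood ratio"
  } else {
    "omega"
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1000,
                                        y = .data$statistic)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "position (kb)", y = ylab)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold$cutoff,
                                 linetype = "dashed", colour = "grey40")
  }
  if (!is.null(x_sel)) {
    p <- p + ggplot2::geom_vline(xintercept = x_sel / 1000,
                                 linetype = "dotted", colour = "red")
  }
  p
}

#' Plot a conditioned allele-frequency trajectory
#'
#' @param object A [simulate_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_path <- function(object, ...) {
  df <- tibble(time = object$times, frequency = object$freqs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time before sampling (2N generations)",
                  y = "beneficial-allele frequency")
}

#' @export
tidy.trajectory_path <- function(x, ...) {
  tibble(time = x$times, frequency = x$freqs)
}

#' Plot true/false-positive rates of a power study
#'
#' @param object A [run_power_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_table <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("tp_pct", "fp_pct"),
                            names_to = "rate", values_to = "pct")
  df$rate <- ifelse(df$rate == "tp_pct", "true positive", "false positive")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$pct,
                                   fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~statistic) +
    ggplot2::labs(x = NULL, y = "rate (%)", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot LD decay summaries
#'
#' Median (solid), mean (dashed) and 95th percentile (dotted) of pairwise
#' `r^2` per physical-distance bin.
#'
#' @param decay A [ld_decay()] table.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(decay) {
  ggplot2::ggplot(decay, ggplot2::aes(x = .data$bin_mid / 1000)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_r2), linetype = "solid") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_r2), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$q95_r2), linetype = "dotted") +
    ggplot2::labs(x = "distance (kb)", y = expression(r^2))
}
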