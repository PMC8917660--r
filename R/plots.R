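## ggplot2 visualizations for the main result types.

#' Polar plot of limb phases by speed bin
#'
#' The radial axis is the speed bin; the angle is the circular-mean phase
#' of each limb at front-right cycle starts (front right is the reference
#' at 0).
#'
#' @param object a `gait_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gait_summary <- function(object, ...) {
  df <- object$by_speed |>
    tidyr::pivot_longer(dplyr::all_of(c("mean_fl", "mean_hl", "mean_hr")),
                        names_to = "limb", values_to = "phase") |>
    dplyr::mutate(limb = toupper(sub("mean_", "", .data$limb)),
                  bin = as.integer(.data$speed_bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$bin,
                                   colour = .data$limb, size = .data$n)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 2 * pi),
                                breaks = c(0, pi / 2, pi, 3 * pi / 2),
                                labels = c("0", "π/2", "π", "3π/2")) +
    ggplot2::labs(x = "limb phase at FR cycle start (rad)",
                  y = "speed bin", colour = "limb", size = "strides") +
    ggplot2::theme_minimal()
}

#' Heatmap of behavioral fingerprints
#'
#' @param object a `fingerprint_set`.
#' @param ... unused.
#' @return a ggplot object (body-part channel x frequency, faceted by class).
#' @export
autoplot.fingerprint_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(signif(.data$freq, 3)),
                                       y = .data$channel,
                                       fill = .data$mean_power)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "frequency (Hz)", y = "body-part channel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Usage-over-time habituation curves with confidence bands
#'
#' @param usage_ts output of [usage_over_time()].
#' @param classes optional subset of classes to show.
#' @return a ggplot object.
#' @export
plot_usage_over_time <- function(usage_ts, classes = NULL) {
  df <- usage_ts
  if (!is.null(classes)) df <- dplyr::filter(df, .data$class %in% classes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_mid_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "time in trial (s)", y = "usage fraction") +
    ggplot2::theme_minimal()
}

#' Ethogram raster of coarse labels over time
#'
#' @param eth ethogram tibble.
#' @param frame_rate Hz.
#' @return a ggplot object.
#' @export
plot_ethogram <- function(eth, frame_rate) {
  runs <- rle_runs(eth$coarse)
  runs$t0 <- (runs$start - 1) / frame_rate
  runs$t1 <- runs$end / frame_rate
  ggplot2::ggplot(runs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$t0, xmax = .data$t1,
                                    ymin = 0, ymax = 1, fill = .data$value)) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "class") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Log-ratio difference interval plot
#'
#' @param object a `logratio_ci`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.logratio_ci <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$behavior, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = NULL, y = "clr log-ratio difference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
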