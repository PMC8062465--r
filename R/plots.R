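# ggplot2 autoplot methods for the result classes

#' Plot a titration fit
#'
#' Titration points and the fitted two-state curve on a log10 intensity
#' scale.
#'
#' @param object A `birn_titration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.birn_titration_fit <- function(object, ...) {
  d <- object$data
  d$unit_intensity <- d$intensity / d$concentration
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$ph, y = .data$unit_intensity)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pH", y = "intensity / concentration (a.u.)",
                  title = sprintf("Titration fit: %s", object$channel))
  if (!object$flat) {
    grid <- tibble(ph = seq(min(d$ph), max(d$ph), length.out = 200))
    grid$fit <- object$f_min_hat +
      (object$f_max_hat - object$f_min_hat) *
      theta_on(grid$ph, object$ph_t_hat, object$width_10_90_hat)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$ph, y = .data$fit),
                                colour = "firebrick")
  }
  p
}

#' Plot a calibration curve
#'
#' Per-level mean O/A ratios with the fitted line.
#'
#' @param object A `birn_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.birn_calibration <- function(object, ...) {
  ggplot2::ggplot(object$levels,
                  ggplot2::aes(x = .data$f_on * 100, y = .data$mean_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope / 100, colour = "firebrick") +
    ggplot2::labs(x = "turn-ON percentage", y = "O/A ratio",
                  title = sprintf("Calibration (%s): r = %.4f",
                                  object$tissue, object$r))
}

#' Plot an internalization kinetics fit
#'
#' Time-course points and the fitted mono-exponential with the half-time
#' marked.
#'
#' @param object A `birn_kinetics_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.birn_kinetics_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(time = seq(0, max(d$time), length.out = 200))
  grid$fit <- object$plateau * (1 - exp(-object$k * grid$time))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = "dashed") +
    ggplot2::labs(x = sprintf("time (%s)", object$unit), y = "ON fraction",
                  title = sprintf("t_half = %.2f %s", object$t_half,
                                  object$unit))
}

#' Plot a dose-response fit
#'
#' Viability against log10 concentration with the fitted 4PL curve and
#' the IC50 marked.
#'
#' @param object A `birn_dose_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.birn_dose_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(lc = seq(min(d$lc), max(d$lc), length.out = 200))
  grid$fit <- object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (grid$lc - log10(object$ic50))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lc, y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = log10(object$ic50), linetype = "dashed") +
    ggplot2::labs(x = "log10 concentration", y = "viability",
                  title = sprintf("IC50 = %.3g", object$ic50))
}

#' Raster plot of a ratio image or binary mask
#'
#' @param x A `birn_ratio` result or a binary matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ratio_image <- function(x, ...) {
  m <- if (inherits(x, "birn_ratio")) x$ratio else x
  d <- tidyr::expand_grid(row = seq_len(nrow(m)) - 1L,
                          col = seq_len(ncol(m)) - 1L)
  d$value <- as.vector(t(m))  # row-major to match expand_grid order
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "col", y = "row", fill = "O/A")
}
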