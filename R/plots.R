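#' Plot a phase-cycle profile
#'
#' Magnitude of the complex pc-bSSFP signal versus RF phase increment, with
#' the Fourier-interpolated frequency response overlaid.
#'
#' @param object A `bssfp_profile`.
#' @param upsample Interpolation factor for the dense curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bssfp_profile <- function(object, upsample = 32L, ...) {
  up <- fourier_upsample(Mod(object$signal), object$phase_increment, upsample)
  dense <- tibble(phase = up$grid %% (2 * pi), magnitude = up$values)
  ggplot2::ggplot(dense, ggplot2::aes(.data$phase, .data$magnitude)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(
      data = tibble(phase = object$phase_increment,
                    magnitude = Mod(object$signal)),
      colour = "firebrick") +
    ggplot2::labs(x = "RF phase increment (rad)", y = "|S|",
                  title = "pc-bSSFP frequency response") +
    ggplot2::theme_minimal()
}

#' Plot a binned orientation curve
#'
#' @param object A `binned_curve` from [bin_parameter()].
#' @param ... Unused.
#' @return A ggplot (mean +/- SD per angle bin, faceted by FA stratum when
#'   more than one is present).
#' @export
autoplot.binned_curve <- function(object, ...) {
  df <- dplyr::filter(object, .data$n > 0)
  df$fa_label <- sprintf("FA [%.2f, %.2f)", df$fa_lo, df$fa_hi)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$angle_mid, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fiber-to-field angle (deg)",
                  y = attr(object, "value") %||% "parameter") +
    ggplot2::theme_minimal()
  if (length(unique(df$fa_label)) > 1)
    p <- p + ggplot2::facet_wrap(~fa_label)
  p
}

#' Plot an orientation-dependence model fit
#'
#' @param object An `orientation_fit`.
#' @param ... Unused.
#' @return A ggplot of the binned data with the fitted curve.
#' @export
autoplot.orientation_fit <- function(object, ...) {
  dense <- tibble(angle = seq(0, 90, by = 0.5))
  dense$value <- predict(object, tibble(angle_mid = dense$angle))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$angle, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = dense, colour = "steelblue") +
    ggplot2::labs(x = "angle (deg)", y = object$target,
                  subtitle = sprintf("%s, R^2 = %.3f", object$model,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a substrate or its field map
#'
#' @param object An `axon_substrate` or `field_map`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.axon_substrate <- function(object, ...) {
  df <- grid_to_df(object$labels, object$px)
  df$compartment <- factor(df$value, levels = c(0, 1, 2),
                           labels = c("extra-axonal", "intra-axonal", "myelin"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c("grey90", "steelblue", "grey25")) +
    ggplot2::labs(x = "um", y = "um") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.axon_substrate
#' @export
autoplot.field_map <- function(object, ...) {
  df <- grid_to_df(object$offset * 1e6, object$px)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_gradient2(name = "dB/B0 (ppm)") +
    ggplot2::labs(x = "um", y = "um",
                  title = sprintf("theta = %g deg", object$theta)) +
    ggplot2::theme_minimal()
}

grid_to_df <- function(mat, px) {
  n1 <- nrow(mat); n2 <- ncol(mat)
  tibble(x = rep((seq_len(n1) - 0.5) * px, times = n2),
         y = rep((seq_len(n2) - 0.5) * px, each = n1),
         value = as.vector(mat))
}

#' Plot R1/R2 orientation sweeps
#'
#' @param sweep Tibble from [theta_sweep()].
#' @param rate `"R2"` or `"R1"`.
#' @return A ggplot of the rate versus angle per compartment.
#' @export
plot_theta_sweep <- function(sweep, rate = "R2") {
  ggplot2::ggplot(sweep,
                  ggplot2::aes(.data$theta, .data[[rate]],
                               colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fiber-to-field angle (deg)", y = paste(rate, "(1/s)")) +
    ggplot2::theme_minimal()
}
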