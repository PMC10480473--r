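# Quick-look ggplot2 figures for the result objects.

#' @export
autoplot.axial_profile <- function(object, log_y = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z * 1000,
                                            y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "normalized intensity",
                  title = attr(object, "backend"))
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.fluence_field <- function(object, ...) {
  df <- tidy(object)
  df$log_phi <- log10(pmax(df$phi, max(df$phi) * 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1000, y = .data$z * 1000,
                                   fill = .data$log_phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "r (mm)", y = "depth (mm)",
                  fill = "log10 fluence\n(W/m^2)") +
    ggplot2::coord_cartesian(expand = FALSE)
}

#' @export
autoplot.mc_tally <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$fluence), , drop = FALSE]
  df$log_phi <- log10(pmax(df$fluence, max(df$fluence) * 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r * 1000, y = .data$z * 1000,
                                   fill = .data$log_phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "r (mm)", y = "depth (mm)",
                  fill = "log10 fluence\n(W/m^2)") +
    ggplot2::coord_cartesian(expand = FALSE)
}

#' @export
autoplot.temperature_result <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$t,
                                              y = .data$T_max_rise)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "max temperature rise (K)")
}

#' @export
autoplot.optics_comparison <- function(object, log_y = TRUE, ...) {
  df <- tibble(
    z = rep(object$z, 3),
    value = c(object$beer_lambert, object$diffusion, object$montecarlo),
    backend = rep(c("beer_lambert", "diffusion", "montecarlo"),
                  each = nrow(object)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z * 1000, y = .data$value,
                                        colour = .data$backend)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "normalized intensity")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plateau-rise sweep figure
#'
#' @param sweep A tibble from [power_sweep()], [waist_sweep()] or
#'   [duty_cycle_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  xvar <- setdiff(names(sweep), c("plateau_rise", "frequency"))[1]
  p <- ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[xvar]],
                                           y = .data$plateau_rise)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(y = "plateau max rise (K)")
  if ("frequency" %in% names(sweep) && length(unique(sweep$frequency)) > 1) {
    p <- p + ggplot2::aes(colour = factor(.data$frequency)) +
      ggplot2::labs(colour = "pulse frequency (Hz)")
  }
  p
}
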