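# broom-style tidy()/glance() methods for the result objects.

#' @export
tidy.fluence_field <- function(x, ...) {
  grid_tibble(x$grid, phi = x$phi, q_abs = x$q_abs)
}

#' @export
glance.fluence_field <- function(x, ...) {
  tibble(
    incident_power = x$incident_power,
    absorbed_power = x$absorbed_power,
    escaped_fraction = x$escaped_fraction,
    residual = x$residual,
    n_cells = x$grid$nr * x$grid$nz,
    convention = x$settings$diffusion_convention
  )
}

#' @export
tidy.mc_tally <- function(x, ...) {
  grid_tibble(x$grid, fluence = x$phi, stderr = x$phi_se,
              absorbed_weight = x$absorbed)
}

#' @export
glance.mc_tally <- function(x, ...) {
  tibble(
    n_photons = x$settings$n_photons,
    seed = x$settings$seed,
    specular = unname(x$fractions["specular"]),
    diffuse_reflected = unname(x$fractions["diffuse_reflected"]),
    transmitted = unname(x$fractions["transmitted"]),
    absorbed = unname(x$fractions["absorbed"]),
    roulette_residual = x$roulette_residual
  )
}

#' @export
tidy.temperature_result <- function(x, ...) {
  x$series
}

#' @export
glance.temperature_result <- function(x, ...) {
  late <- x$series[x$series$t >= 0.9 * max(x$series$t), , drop = FALSE]
  slope <- if (nrow(late) >= 2) {
    coef(lm(T_max_rise ~ t, data = late))[["t"]]
  } else NA_real_
  tibble(
    t_end = max(x$series$t),
    final_max_rise = tail(x$series$T_max_rise, 1),
    late_slope = slope,
    scheme = x$settings$scheme,
    pulsed = !is_continuous(x$schedule)
  )
}

#' @export
tidy.plateau_field <- function(x, ...) {
  grid_tibble(x$grid, T_rise = x$rise)
}

#' @export
glance.plateau_field <- function(x, ...) {
  tibble(max_rise = x$max_rise, duty = x$duty)
}
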