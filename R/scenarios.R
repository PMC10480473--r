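# Packaged exposure scenarios, parametric sweep drivers, and a synthetic
# stack generator for property tests.

scenario_names <- c("thz_130ghz", "thz_1thz", "nir_1030nm", "bacon")

#' Load a packaged exposure scenario
#'
#' Returns one of the shipped scenario configurations:
#' `"thz_130ghz"` (sub-THz 6G band; mu_a 50/70/7 per cm, no scattering),
#' `"thz_1thz"` (mu_a 137/140/25 per cm), `"nir_1030nm"` (near-infrared,
#' scattering-dominated; editable literature-style coefficients), and
#' `"bacon"` (non-living tissue bench exposure, effective 2 cm focal spot).
#'
#' @param name Scenario name.
#' @return A `scenario_config` (see [read_scenario()]).
#' @export
#' @examples
#' cfg <- scenario("thz_130ghz")
#' config_stack(cfg)
scenario <- function(name) {
  if (length(name) != 1 || !name %in% scenario_names) {
    abort(sprintf("unknown scenario '%s'; choices: %s",
                  paste(name, collapse = ","),
                  paste(scenario_names, collapse = ", ")))
  }
  path <- system.file("scenarios", paste0(name, ".yaml"),
                      package = "skintherm", mustWork = TRUE)
  read_scenario(path)
}

# one coupled optics -> plateau evaluation used by all sweep drivers
coupled_plateau <- function(config, power = NULL, waist = NULL,
                            schedule = NULL) {
  if (!is.null(waist)) {
    # keep the domain at least three beam waists wide as the beam grows
    config$grid$r_max_mm <- max(config$grid$r_max_mm, 3 * waist * 1000)
  }
  stack <- config_stack(config)
  grid <- config_grid(config)
  source <- config_source(config)
  if (!is.null(power)) source$power <- power
  if (!is.null(waist)) source$waist <- waist
  field <- solve_fluence(stack, source, grid, config_diffusion_settings(config))
  q_heat <- absorbed_power_density(field, power = source$power)
  boundary <- config_boundary(config)
  if (is.null(schedule) || is_continuous(schedule)) {
    plateau_rise(stack, grid, boundary, q_heat)$max_rise
  } else {
    as.numeric(pulsed_plateau_rise(stack, grid, boundary, q_heat, schedule))
  }
}

#' Plateau temperature rise as a function of source power
#'
#' One coupled optics + stationary bioheat evaluation per power. The
#' discrete system is linear in the source, so rises scale exactly with
#' power; the sweep makes that auditable.
#'
#' @param config A `scenario_config`.
#' @param powers Beam powers, W (> 0); order preserved.
#' @return Tibble with `power` (W) and `plateau_rise` (K).
#' @export
power_sweep <- function(config, powers) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(powers <= 0)) abort("`powers` must be > 0")
  purrr::map_dfr(powers, function(p) {
    tibble(power = p, plateau_rise = coupled_plateau(config, power = p))
  })
}

#' Plateau temperature rise as a function of beam waist
#'
#' At fixed power the plateau rise decreases with waist: spreading the beam
#' lowers the power density quadratically, partially offset by lateral heat
#' conduction, so the decrease is sub-quadratic but strictly monotone.
#'
#' @param config A `scenario_config`.
#' @param waists Beam waists, m (> 0); order preserved.
#' @return Tibble with `waist` (m) and `plateau_rise` (K).
#' @export
waist_sweep <- function(config, waists) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(waists <= 0)) abort("`waists` must be > 0")
  purrr::map_dfr(waists, function(w) {
    tibble(waist = w, plateau_rise = coupled_plateau(config, waist = w))
  })
}

#' Plateau rise over duty cycles and pulse frequencies
#'
#' For each duty/frequency pair, computes the asymptotic per-cycle maximum
#' rise of the square-wave-modulated exposure. The plateau scales with the
#' duty cycle and is essentially independent of the repetition frequency
#' (the thermal time constants are far longer than any 1-100 Hz period).
#'
#' @param config A `scenario_config`.
#' @param duties Duty cycles in `(0, 1]`; 1 is the continuous source.
#' @param frequencies Pulse repetition rates, Hz.
#' @return Tibble with `duty_cycle`, `frequency`, `plateau_rise` (K), one
#'   row per combination (continuous rows keep `frequency` as given).
#' @export
duty_cycle_sweep <- function(config, duties, frequencies = 1) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(duties <= 0 | duties > 1)) abort("`duties` must lie in (0, 1]")
  if (any(frequencies <= 0)) abort("`frequencies` must be > 0")
  grid_df <- expand.grid(duty_cycle = duties, frequency = frequencies,
                         KEEP.OUT.ATTRS = FALSE)
  purrr::pmap_dfr(grid_df, function(duty_cycle, frequency) {
    sched <- pulse_schedule(duty_cycle, frequency)
    tibble(duty_cycle = duty_cycle, frequency = frequency,
           plateau_rise = coupled_plateau(config, schedule = sched))
  })
}

#' Generate a reproducible random layered stack
#'
#' Property-test input generator: layer thicknesses and optical/thermal
#' coefficients drawn uniformly from the given ranges, with a fixed seed so
#' identical calls give identical stacks.
#'
#' @param seed RNG seed.
#' @param n_layers Number of layers (>= 1).
#' @param mu_a_range,mu_s_prime_range Coefficient ranges, 1/m.
#' @param thickness_range Layer thickness range, m.
#' @param g_range Anisotropy range within `[0, 1)`.
#' @return A [tissue_stack()] with layers named `synthetic_1`, ...
#' @export
synth_stack <- function(seed, n_layers = 3,
                        mu_a_range = c(100, 10000),
                        mu_s_prime_range = c(0, 0),
                        thickness_range = c(2e-4, 2e-3),
                        g_range = c(0, 0)) {
  if (n_layers < 1) abort("`n_layers` must be >= 1")
  check_range <- function(r, name, lo = 0, hi = Inf) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      abort(sprintf("`%s` must be an ordered range within [%g, %g)",
                    name, lo, hi))
    }
  }
  check_range(mu_a_range, "mu_a_range")
  check_range(mu_s_prime_range, "mu_s_prime_range")
  check_range(thickness_range, "thickness_range", lo = 1e-12)
  check_range(g_range, "g_range", hi = 1)
  if (g_range[2] >= 1) abort("`g_range` must stay below 1")
  withr::with_seed(seed, {
    runif_in <- function(r) stats::runif(n_layers, r[1], r[2])
    tissue_stack(tibble(
      name = paste0("synthetic_", seq_len(n_layers)),
      thickness = runif_in(thickness_range),
      mu_a = runif_in(mu_a_range),
      mu_s_prime = runif_in(mu_s_prime_range),
      g = runif_in(g_range),
      n = 1,
      rho = 1050, c_p = 3600, k = 0.5,
      perfused = TRUE
    ))
  })
}
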