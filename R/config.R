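# Scenario configuration files. YAML with unit-suffixed keys, holding the
# values in the units the field customarily prints (mm, cm^-1); conversion
# to SI happens exactly once, in the accessors that build solver objects.
#
# Schema (all keys required unless marked optional):
#   name: label
#   stack:
#     layers: list of {name, thickness_mm, mu_a_per_cm, mu_s_prime_per_cm,
#                      g, n, rho_kg_m3, c_p_J_per_kgK, k_W_per_mK, perfused}
#     blood: {rho_b_kg_m3, c_pb_J_per_kgK, omega_b_per_s, T_b_K,
#             q_met_W_per_m3}
#   source: {power_W, waist_mm, profile, duty_cycle, pulse_frequency_Hz}
#           (duty_cycle 1 = continuous)
#   grid: {dr_mm, dz_mm (scalar or one per layer), r_max_mm}
#   thermal: {h_W_per_m2K, T_ambient_K, dt_s, t_end_s}
#   optics: {backend, convention, far_boundary, mc_n_photons, mc_seed,
#            mc_ambient_n}

config_schema <- list(
  stack = c("layers", "blood"),
  source = c("power_W", "waist_mm", "profile", "duty_cycle",
             "pulse_frequency_Hz"),
  grid = c("dr_mm", "dz_mm", "r_max_mm"),
  thermal = c("h_W_per_m2K", "T_ambient_K", "dt_s", "t_end_s"),
  optics = c("backend", "convention", "far_boundary", "mc_n_photons",
             "mc_seed", "mc_ambient_n")
)

layer_keys <- c("name", "thickness_mm", "mu_a_per_cm", "mu_s_prime_per_cm",
                "g", "refractive_index", "rho_kg_m3", "c_p_J_per_kgK",
                "k_W_per_mK", "perfused")
blood_keys <- c("rho_b_kg_m3", "c_pb_J_per_kgK", "omega_b_per_s", "T_b_K",
                "q_met_W_per_m3")

#' Read a scenario configuration file
#'
#' Parses and validates a scenario YAML (see the package vignette for the
#' schema). Validation errors name the offending key.
#'
#' @param path Path to a scenario YAML file.
#' @return A `scenario_config` list mirroring the file.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  validate_scenario_config(raw, path)
  structure(c(raw, list(.path = normalizePath(path))),
            class = "scenario_config")
}

validate_scenario_config <- function(raw, path = "<config>") {
  bad <- function(key) {
    abort(sprintf("config %s: missing or invalid key `%s`", path, key))
  }
  if (is.null(raw$name)) bad("name")
  for (section in names(config_schema)) {
    if (is.null(raw[[section]])) bad(section)
    for (key in config_schema[[section]]) {
      if (is.null(raw[[c(section, key)]])) bad(paste(section, key, sep = "."))
    }
  }
  layers <- raw$stack$layers
  if (!length(layers)) bad("stack.layers")
  for (i in seq_along(layers)) {
    for (key in layer_keys) {
      if (is.null(layers[[i]][[key]])) {
        bad(sprintf("stack.layers[%d].%s", i, key))
      }
    }
  }
  for (key in blood_keys) {
    if (is.null(raw$stack$blood[[key]])) bad(paste0("stack.blood.", key))
  }
  if (!raw$optics$backend %in% c("beer_lambert", "diffusion", "montecarlo")) {
    abad <- sprintf(
      "config %s: optics.backend must be one of beer_lambert, diffusion, montecarlo",
      path)
    abort(abad)
  }
  ndz <- length(raw$grid$dz_mm)
  if (ndz != 1 && ndz != length(layers)) {
    bad("grid.dz_mm (scalar or one value per layer)")
  }
  invisible(raw)
}

#' Write a scenario configuration file
#'
#' Numbers are written with 17 significant digits so a write/read round trip
#' reproduces every value bit-exactly.
#'
#' @param config A `scenario_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- unclass(config)
  out$.path <- NULL
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> '%s': %d layer(s), %s backend, %g W / %g mm waist\n",
              x$name, length(x$stack$layers), x$optics$backend,
              x$source$power_W, x$source$waist_mm))
  invisible(x)
}

# ---- accessors: config (customary units) -> solver objects (SI) ----------

#' Build solver objects from a scenario config
#'
#' `config_stack()`, `config_source()`, `config_grid()`, `config_boundary()`,
#' `config_thermal_settings()`, `config_diffusion_settings()` and
#' `config_mc_settings()` convert the unit-suffixed config values to the SI
#' objects the solvers consume.
#'
#' @param config A `scenario_config` from [read_scenario()] or [scenario()].
#' @return The corresponding solver object.
#' @export
config_stack <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- purrr::map_dfr(config$stack$layers, function(ly) {
    layer(ly$name, ly$thickness_mm, ly$mu_a_per_cm, ly$mu_s_prime_per_cm,
          g = ly$g, n = ly$refractive_index, rho = ly$rho_kg_m3,
          c_p = ly$c_p_J_per_kgK, k = ly$k_W_per_mK,
          perfused = isTRUE(ly$perfused))
  })
  bl <- config$stack$blood
  tissue_stack(rows, blood_model(
    rho_b = bl$rho_b_kg_m3, c_pb = bl$c_pb_J_per_kgK,
    omega_b = bl$omega_b_per_s, T_b = bl$T_b_K, q_met = bl$q_met_W_per_m3))
}

#' @rdname config_stack
#' @export
config_source <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  s <- config$source
  pulse <- if (s$duty_cycle < 1) {
    pulse_schedule(s$duty_cycle, s$pulse_frequency_Hz)
  }
  gaussian_source(s$power_W, s$waist_mm / 1000, pulse = pulse)
}

#' @rdname config_stack
#' @export
config_grid <- function(config) {
  stack <- config_stack(config)
  axi_grid(stack, dr = config$grid$dr_mm / 1000,
           dz = unlist(config$grid$dz_mm) / 1000,
           r_max = config$grid$r_max_mm / 1000)
}

#' @rdname config_stack
#' @export
config_boundary <- function(config) {
  thermal_boundary(h = config$thermal$h_W_per_m2K,
                   T_ambient = config$thermal$T_ambient_K)
}

#' @rdname config_stack
#' @export
config_thermal_settings <- function(config) {
  thermal_settings(dt = config$thermal$dt_s, t_end = config$thermal$t_end_s)
}

#' @rdname config_stack
#' @export
config_diffusion_settings <- function(config) {
  diffusion_settings(diffusion_convention = config$optics$convention,
                     far_boundary = config$optics$far_boundary)
}

#' @rdname config_stack
#' @export
config_mc_settings <- function(config, n_photons = NULL, seed = NULL) {
  mc_settings(n_photons = n_photons %||% config$optics$mc_n_photons,
              seed = seed %||% config$optics$mc_seed,
              ambient_n = config$optics$mc_ambient_n)
}
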