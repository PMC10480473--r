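# End-to-end coupled runs: optics backend -> absorbed power density ->
# transient Pennes solve, with a reproducibility manifest and CSV/JSON
# exports.

#' Absorbed power density driving the bioheat solver
#'
#' Converts an optics result into the volumetric heat source, W/m^3, on its
#' grid. Under the no-reflection assumption the entire beam power enters the
#' tissue, so the deposition profile of the backend is scaled to deliver the
#' full beam power (minus the fraction that escapes through the far
#' boundaries): for the diffusion backend the Dirichlet solution fixes the
#' *shape* of the deposition and the amplitude is normalized to the beam
#' power; Monte Carlo tallies are already absolute.
#'
#' @param field A `fluence_field` or `mc_tally`.
#' @param power Beam power to deliver, W; defaults to the source power the
#'   field was computed with.
#' @return `nr x nz` matrix of absorbed power density, W/m^3.
#' @export
absorbed_power_density <- function(field, power = NULL) {
  UseMethod("absorbed_power_density")
}

#' @export
absorbed_power_density.fluence_field <- function(field, power = NULL) {
  power <- power %||% field$source$power
  if (power == 0 || field$incident_power == 0) {
    return(matrix(0, field$grid$nr, field$grid$nz))
  }
  field$q_abs * (power / field$incident_power)
}

#' @export
absorbed_power_density.mc_tally <- function(field, power = NULL) {
  power <- power %||% field$source$power
  vol <- cell_volumes(field$grid)
  power * field$absorbed /
    (field$accounted_weight * field$settings$n_photons * vol)
}

# Beer-Lambert heat source: the 1D attenuation treats scattering as
# absorption, so the cell-averaged deposition in a z-cell is the difference
# of the survival function across it, radially weighted by the beam profile.
beer_lambert_q_abs <- function(stack, source, grid) {
  tab <- bl_tau_table(stack)
  z_lo <- head(grid$z_edges, -1); z_hi <- tail(grid$z_edges, -1)
  idx <- grid$layer_index
  tau_at <- function(z) {
    i <- pmin(findInterval(z, interface_depths(stack)), nrow(stack))
    tab$tau_top[i] + tab$mu_t[i] * (z - tab$tops[i])
  }
  dep <- (exp(-tau_at(z_lo)) - exp(-tau_at(z_hi))) / grid$dz  # 1/m
  # beam power through each annulus, integrated exactly, as mean irradiance
  r_lo <- head(grid$r_edges, -1); r_hi <- tail(grid$r_edges, -1)
  w <- source$waist
  p_ann <- source$power * (exp(-2 * r_lo^2 / w^2) - exp(-2 * r_hi^2 / w^2))
  irr <- p_ann / grid$area_z                                  # W/m^2
  outer(irr, dep)
}

backend_choices <- c("beer_lambert", "diffusion", "montecarlo")

run_optics <- function(config, backend, stack, source, grid, seed = NULL) {
  switch(
    backend,
    diffusion = {
      field <- solve_fluence(stack, source, grid,
                             config_diffusion_settings(config))
      list(field = field,
           q_heat = absorbed_power_density(field, power = source$power),
           centerline = centerline_profile(field),
           diagnostics = list(
             incident_power = field$incident_power,
             escaped_fraction = field$escaped_fraction,
             residual = field$residual))
    },
    montecarlo = {
      tally <- run_mc(stack, source, grid,
                      config_mc_settings(config, seed = seed))
      list(field = tally,
           q_heat = absorbed_power_density(tally, power = source$power),
           centerline = centerline_profile(tally),
           diagnostics = list(
             weight_fractions = as.list(tally$fractions),
             roulette_residual = tally$roulette_residual,
             mc_seed = tally$settings$seed))
    },
    beer_lambert = {
      prof <- beer_lambert_profile(stack, c(0, grid$z))
      list(field = NULL,
           q_heat = beer_lambert_q_abs(stack, source, grid),
           centerline = prof,
           diagnostics = list(
             transmitted_fraction =
               tail(beer_lambert_fractions(stack)$fraction, 1)))
    },
    abort(sprintf("unknown backend '%s'; choices: %s", backend,
                  paste(backend_choices, collapse = ", ")))
  )
}

#' Run a coupled optics + bioheat scenario
#'
#' Executes the configured optics backend, converts the result to an
#' absorbed-power-density field, integrates the transient Pennes solve with
#' the configured pulse schedule, and (optionally) writes all outputs plus a
#' reproducibility manifest.
#'
#' @param config A `scenario_config` from [scenario()] or [read_scenario()].
#' @param backend Optional override of `config$optics$backend`.
#' @param out_dir Optional output directory; created if missing. Writes
#'   `fluence.csv`, `centerline.csv`, `temperature.csv`, snapshot CSVs and
#'   `manifest.json`.
#' @param seed Optional Monte Carlo seed override.
#' @param optics_only Skip the thermal stage.
#' @return A `scenario_result` list: `optics` (backend result), `q_abs`
#'   (W/m^3), `temperature` (a `temperature_result`, unless `optics_only`),
#'   `plateau` (stationary max rise, K), `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_scenario(scenario("thz_130ghz"), optics_only = TRUE)
#' res$manifest$diagnostics
#' }
run_scenario <- function(config, backend = NULL, out_dir = NULL, seed = NULL,
                         optics_only = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  backend <- backend %||% config$optics$backend
  backend <- match.arg(backend, backend_choices)
  stack <- config_stack(config)
  source <- config_source(config)
  grid <- config_grid(config)

  opt <- run_optics(config, backend, stack, source, grid, seed = seed)

  temperature <- NULL
  plateau <- NA_real_
  if (!optics_only) {
    boundary <- config_boundary(config)
    schedule <- source$pulse
    settings <- config_thermal_settings(config)
    if (!is_continuous(schedule)) {
      on_time <- schedule$duty_cycle / schedule$frequency
      settings$dt <- min(settings$dt, on_time / 10)
    }
    temperature <- solve_transient(stack, grid, boundary, opt$q_heat,
                                   schedule = schedule, settings = settings)
    plateau <- plateau_rise(stack, grid, boundary, opt$q_heat,
                            duty = if (is_continuous(schedule)) 1
                                   else schedule$duty_cycle)$max_rise
  }

  manifest <- list(
    scenario = config$name,
    config_path = config$.path %||% NA_character_,
    config_md5 = if (!is.null(config$.path)) {
      unname(tools::md5sum(config$.path))
    } else NA_character_,
    backend = backend,
    seed = seed %||% config$optics$mc_seed,
    package_version = as.character(utils::packageVersion("skintherm")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    grid = list(nr = grid$nr, nz = grid$nz),
    diagnostics = opt$diagnostics,
    outputs = character(0)
  )

  result <- structure(
    list(optics = opt$field, backend = backend, q_abs = opt$q_heat,
         centerline = opt$centerline, temperature = temperature,
         plateau = plateau, grid = grid, stack = stack, source = source,
         manifest = manifest),
    class = "scenario_result")

  if (!is.null(out_dir)) result <- write_run_outputs(result, out_dir)
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$grid
  paths <- character(0)
  put <- function(df, file) {
    p <- file.path(out_dir, file)
    readr::write_csv(df, p)
    paths <<- c(paths, file)
  }
  if (!is.null(result$optics) && inherits(result$optics, "fluence_field")) {
    put(grid_tibble(grid, phi = result$optics$phi,
                    q_abs = result$optics$q_abs), "fluence.csv")
  } else {
    put(grid_tibble(grid, q_abs = result$q_abs), "fluence.csv")
  }
  cl <- as_tibble(result$centerline)
  names(cl)[1:2] <- c("depth_m", "normalized_intensity")
  put(cl, "centerline.csv")
  if (!is.null(result$temperature)) {
    ser <- result$temperature$series
    names(ser) <- c("t_s", "T_max_rise_K")
    put(ser, "temperature.csv")
    for (nm in names(result$temperature$snapshots)) {
      put(grid_tibble(grid, T_rise = result$temperature$snapshots[[nm]]),
          paste0("snapshot_", gsub("[^0-9a-zA-Z.]", "_", nm), ".csv"))
    }
  }
  result$manifest$outputs <- paths
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  result
}

#' Re-run a scenario from its manifest
#'
#' Reads the manifest of a previous [run_scenario()] output directory and
#' repeats the run with the same config, backend and seed, reproducing all
#' numeric outputs.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Optional output directory for the replay.
#' @return The replayed `scenario_result`.
#' @export
replay_run <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(man$config_path) || !file.exists(man$config_path)) {
    abort("manifest does not point to an existing config file")
  }
  run_scenario(read_scenario(man$config_path), backend = man$backend,
               out_dir = out_dir, seed = man$seed)
}

#' Three-backend centerline comparison
#'
#' Computes the normalized axial intensity profile along the beam axis with
#' the analytical Beer-Lambert model, the diffusion solve, and Monte Carlo,
#' aligned on the axial cell centers of the scenario grid.
#'
#' @param config A `scenario_config`.
#' @param n_photons Optional Monte Carlo photon count override.
#' @param seed Optional Monte Carlo seed override.
#' @return An `optics_comparison` tibble: `z` (m), `beer_lambert`,
#'   `diffusion`, `montecarlo`, `mc_stderr`.
#' @export
compare_optics <- function(config, n_photons = NULL, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  stack <- config_stack(config)
  source <- config_source(config)
  grid <- config_grid(config)

  bl <- beer_lambert_profile(stack, grid$z)
  field <- solve_fluence(stack, source, grid,
                         config_diffusion_settings(config))
  diff_prof <- field$phi[1, ] / field$surface_phi[1]
  tally <- run_mc(stack, source, grid,
                  config_mc_settings(config, n_photons = n_photons,
                                     seed = seed))
  mc_prof <- centerline_profile(tally)

  structure(
    tibble(z = grid$z,
           beer_lambert = bl$value,
           diffusion = diff_prof,
           montecarlo = mc_prof$value,
           mc_stderr = mc_prof$stderr),
    class = c("optics_comparison", class(tibble())))
}
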