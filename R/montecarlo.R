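# Monte Carlo photon transport (validation backend). The compiled kernel in
# src/mc.cpp does the hop/drop/spin work; this file holds settings, the
# user-facing runner, the scattering/Fresnel primitives, and tally summaries.

#' Monte Carlo transport settings
#'
#' @param n_photons Number of photon packets (>= 1).
#' @param seed RNG seed; identical seed and settings give bit-identical
#'   tallies.
#' @param roulette_threshold Weight below which Russian roulette triggers.
#' @param roulette_survival Survival probability of the roulette (survivors'
#'   weight is boosted by its inverse, keeping the game unbiased).
#' @param ambient_n Refractive index of the half-space above the tissue
#'   (and below it). Set equal to the layer indices for the reflection-free
#'   comparison mode used against the diffusion backend.
#' @param n_batch Number of statistically independent photon batches used
#'   for per-cell standard errors.
#' @return An `mc_settings` list.
#' @export
mc_settings <- function(n_photons = 1e5, seed = 1L,
                        roulette_threshold = 1e-4, roulette_survival = 0.1,
                        ambient_n = 1, n_batch = 16L) {
  if (!is.numeric(n_photons) || n_photons < 1) {
    abort("`n_photons` must be >= 1")
  }
  if (roulette_threshold <= 0 || roulette_threshold >= 1) {
    abort("`roulette_threshold` must lie in (0, 1)")
  }
  if (roulette_survival <= 0 || roulette_survival >= 1) {
    abort("`roulette_survival` must lie in (0, 1)")
  }
  if (ambient_n < 1) abort("`ambient_n` must be >= 1")
  structure(
    list(n_photons = as.integer(n_photons), seed = as.integer(seed),
         roulette_threshold = roulette_threshold,
         roulette_survival = roulette_survival,
         ambient_n = ambient_n,
         n_batch = as.integer(max(2L, n_batch))),
    class = "mc_settings"
  )
}

#' Run layered Monte Carlo photon transport
#'
#' Photons are launched at z = 0 in collimated normal incidence with radial
#' position sampled from the Gaussian beam intensity profile. Step lengths
#' are `-log(U) / (mu_a + mu_s)`; at each interaction a `mu_a / (mu_a + mu_s)`
#' share of the weight is deposited in the local grid cell; directions update
#' by Henyey-Greenstein sampling; refractive-index mismatches reflect/refract
#' by the unpolarized Fresnel coefficients; low weights undergo Russian
#' roulette. The full scattering coefficient is derived from the configured
#' reduced one, `mu_s = mu_s' / (1 - g)`.
#'
#' The four weight fractions (specular, diffuse reflectance, transmittance,
#' absorbed) are normalized by the accounted weight, so they sum to 1
#' exactly; the (tiny, zero-mean) roulette residual is reported in
#' `glance()`.
#'
#' @param stack A [tissue_stack()].
#' @param source A [gaussian_source()]; only power and waist are used (pulse
#'   modulation applies to the thermal stage).
#' @param grid An [axi_grid()] for scoring; photons leaving it radially keep
#'   propagating and their absorbed weight is booked per layer off-grid.
#' @param settings An [mc_settings()].
#' @return An `mc_tally` with the absorbed-weight matrix, derived fluence
#'   `phi` (W/m^2, `NA` where `mu_a = 0`), per-cell standard errors, and the
#'   weight fractions.
#' @export
run_mc <- function(stack, source, grid, settings = mc_settings()) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(source, "source_spec"),
            inherits(grid, "axi_grid"), inherits(settings, "mc_settings"))
  check_grid_alignment(grid, stack)
  if (all(stack$mu_a + stack$mu_s_prime <= 0)) {
    abort("Monte Carlo needs mu_a + mu_s > 0 in at least one layer")
  }

  raw <- withr::with_seed(settings$seed, mc_transport_cpp(
    z_bound = interface_depths(stack),
    mu_a = stack$mu_a, mu_s = mu_s_full(stack), g_hg = stack$g,
    n_layer = stack$n, n_above = settings$ambient_n,
    n_below = settings$ambient_n,
    waist = source$waist, r_edges = grid$r_edges, z_edges = grid$z_edges,
    n_photons = settings$n_photons, n_batch = settings$n_batch,
    w_threshold = settings$roulette_threshold,
    p_survival = settings$roulette_survival))

  n <- settings$n_photons
  accounted <- raw$specular + raw$diffuse_reflected + raw$transmitted +
    raw$absorbed_total
  fractions <- c(specular = raw$specular, diffuse_reflected =
                   raw$diffuse_reflected, transmitted = raw$transmitted,
                 absorbed = raw$absorbed_total) / accounted

  # per-layer absorbed weight: on-grid cells plus the off-grid overflow
  on_grid <- vapply(seq_len(nrow(stack)), function(l) {
    cols <- grid$layer_index == l
    sum(raw$absorbed[, cols, drop = FALSE])
  }, numeric(1))
  layer_fraction <- (on_grid + raw$overflow_by_layer) / accounted

  mu_a_cell <- stack$mu_a[grid$layer_index]
  vol <- cell_volumes(grid)
  denom <- sweep(vol, 2, mu_a_cell, `*`) * n
  phi <- source$power * raw$absorbed / denom
  phi_se <- source$power * raw$absorbed_se / denom
  phi[, mu_a_cell == 0] <- NA_real_
  phi_se[, mu_a_cell == 0] <- NA_real_

  structure(
    list(grid = grid, stack = stack, source = source, settings = settings,
         absorbed = raw$absorbed, phi = phi, phi_se = phi_se,
         fractions = fractions,
         layer_fractions = tibble(layer = stack$name,
                                  fraction = layer_fraction),
         roulette_residual = raw$roulette_net / n,
         accounted_weight = accounted / n),
    class = "mc_tally"
  )
}

#' @export
print.mc_tally <- function(x, ...) {
  cat(sprintf(
    "<mc_tally> %g photons (seed %d): specular %.4f, reflected %.4f, transmitted %.4f, absorbed %.4f\n",
    x$settings$n_photons, x$settings$seed, x$fractions["specular"],
    x$fractions["diffuse_reflected"], x$fractions["transmitted"],
    x$fractions["absorbed"]))
  invisible(x)
}

#' Sample the Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the single-scattering polar deflection. For
#' `g = 0` the closed form reduces to the isotropic `2 u - 1`; the sample
#' mean of the cosine equals `g`.
#'
#' @param g Anisotropy factor in `[0, 1)`.
#' @param u Uniform variate(s) in `[0, 1)`.
#' @return Deflection cosine(s) in `[-1, 1]`.
#' @export
#' @examples
#' sample_henyey_greenstein(0, 0.75)  # 0.5
sample_henyey_greenstein <- function(g, u) {
  if (!is.numeric(g) || length(g) != 1 || g < 0 || g >= 1) {
    abort("`g` must lie in [0, 1)")
  }
  if (any(u < 0 | u >= 1)) abort("`u` must lie in [0, 1)")
  if (g == 0) return(2 * u - 1)
  tmp <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - tmp^2) / (2 * g)))
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized power reflectances for a ray crossing
#' from index `n_i` into `n_t` with incidence cosine `cos_i`. Total internal
#' reflection returns 1; matched media return 0.
#'
#' @param n_i,n_t Refractive indices (>= 1).
#' @param cos_i Cosine of the incidence angle, in `[0, 1]`.
#' @return Reflectance(s) in `[0, 1]`.
#' @export
#' @examples
#' fresnel_reflectance(1, 1.4, 1)  # ((1 - 1.4)/(1 + 1.4))^2
fresnel_reflectance <- function(n_i, n_t, cos_i) {
  if (any(n_i < 1) || any(n_t < 1)) abort("refractive indices must be >= 1")
  if (any(cos_i < 0 | cos_i > 1)) abort("`cos_i` must lie in [0, 1]")
  out <- numeric(length(cos_i))
  n_i <- rep_len(n_i, length(cos_i)); n_t <- rep_len(n_t, length(cos_i))
  sin_t2 <- (n_i / n_t)^2 * (1 - cos_i^2)
  tir <- sin_t2 >= 1
  out[tir] <- 1
  if (any(!tir)) {
    ci <- cos_i[!tir]; ct <- sqrt(1 - sin_t2[!tir])
    ni <- n_i[!tir]; nt <- n_t[!tir]
    rs <- ((ni * ci - nt * ct) / (ni * ci + nt * ct))^2
    rp <- ((ni * ct - nt * ci) / (ni * ct + nt * ci))^2
    out[!tir] <- (rs + rp) / 2
  }
  out[n_i == n_t] <- 0
  out
}

#' Centerline fluence profile of a Monte Carlo tally
#'
#' Innermost-ring fluence against depth, normalized at the first tissue
#' cell, with propagated standard errors.
#'
#' @param field An `mc_tally` from [run_mc()].
#' @return An `axial_profile` tibble (`z`, `value`, `stderr`).
#' @export
centerline_profile.mc_tally <- function(field) {
  phi <- field$phi[1, ]
  se <- field$phi_se[1, ]
  if (!any(is.finite(phi)) || all(phi == 0, na.rm = TRUE)) {
    abort("innermost ring is empty; increase n_photons or widen dr")
  }
  norm <- phi[1]
  if (!is.finite(norm) || norm <= 0) {
    abort("first tissue cell scored no weight; increase n_photons")
  }
  new_axial_profile(
    tibble(z = field$grid$z, value = phi / norm, stderr = se / norm),
    backend = "montecarlo")
}
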