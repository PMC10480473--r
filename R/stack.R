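# Layered tissue domain: optical + thermal properties, blood compartment,
# interface bookkeeping. All internal units are SI (m, s, K, W, m^-1);
# converting from the field's customary cm^-1 / mm happens once, at the
# config boundary (see read_scenario()) or in the layer() helper.

#' Blood compartment for the Pennes perfusion term
#'
#' Parameters of the arterial blood pool that exchanges heat with perfused
#' tissue: the volumetric sink/source `rho_b * c_pb * omega_b * (T_b - T)`,
#' plus the baseline metabolic heat generation of tissue.
#'
#' @param rho_b Blood density, kg/m^3.
#' @param c_pb Blood specific heat, J/(kg K).
#' @param omega_b Blood perfusion rate, 1/s. Applied only in layers flagged
#'   `perfused`.
#' @param T_b Arterial blood temperature, K.
#' @param q_met Metabolic volumetric heat generation, W/m^3 (all tissue
#'   layers).
#' @return A `blood_model` list.
#' @export
#' @examples
#' blood_model()
blood_model <- function(rho_b = 1060, c_pb = 3600, omega_b = 1e-3,
                        T_b = 310.15, q_met = 1000) {
  check_positive(rho_b, "rho_b")
  check_positive(c_pb, "c_pb")
  check_nonneg(omega_b, "omega_b")
  check_positive(T_b, "T_b")
  check_nonneg(q_met, "q_met")
  structure(
    list(rho_b = rho_b, c_pb = c_pb, omega_b = omega_b, T_b = T_b,
         q_met = q_met),
    class = "blood_model"
  )
}

#' One tissue layer, in the field's customary units
#'
#' Convenience row constructor: thickness in mm and attenuation coefficients
#' in cm^-1 as usually printed, converted once to SI. For SI input build the
#' layer table directly and pass it to [tissue_stack()].
#'
#' @param name Layer label.
#' @param thickness_mm Layer thickness, mm.
#' @param mu_a_cm Absorption coefficient, cm^-1.
#' @param mu_s_prime_cm Reduced scattering coefficient, cm^-1.
#' @param g Scattering anisotropy (mean cosine), in `[0, 1)`. Only the Monte
#'   Carlo backend distinguishes `g`; it derives `mu_s = mu_s'/(1 - g)`.
#' @param n Refractive index (>= 1); used by the Monte Carlo backend only.
#' @param rho,c_p,k Density (kg/m^3), specific heat (J/(kg K)) and thermal
#'   conductivity (W/(m K)).
#' @param perfused Logical; does the Pennes perfusion sink act in this layer?
#' @return A one-row tibble in SI units, ready for [tissue_stack()].
#' @export
#' @examples
#' layer("epidermis", thickness_mm = 0.2, mu_a_cm = 50)
layer <- function(name, thickness_mm, mu_a_cm, mu_s_prime_cm = 0, g = 0,
                  n = 1, rho = 1050, c_p = 3600, k = 0.5, perfused = FALSE) {
  tibble(
    name = as.character(name),
    thickness = thickness_mm / 1000,
    mu_a = mu_a_cm * 100,
    mu_s_prime = mu_s_prime_cm * 100,
    g = g, n = n, rho = rho, c_p = c_p, k = k,
    perfused = isTRUE(perfused)
  )
}

#' Build a validated layered tissue stack
#'
#' Orders layers top (beam entry, z = 0) to bottom, validates every physical
#' invariant, and records cumulative interface depths. Depth intervals are
#' half-open `[z_top, z_bottom)`: a point exactly on an interface belongs to
#' the layer below it.
#'
#' @param layers A data frame of layers, one row each, with SI columns
#'   `name`, `thickness` (m), `mu_a` (1/m), `mu_s_prime` (1/m), `g`, `n`,
#'   `rho`, `c_p`, `k`, `perfused`. Rows from [layer()] can be combined with
#'   `dplyr::bind_rows()`. Missing thermal columns get the package defaults
#'   (rho 1050, c_p 3600, k 0.5, perfused FALSE; g 0, n 1).
#' @param blood A [blood_model()].
#' @return A `tissue_stack`: a tibble of layers with attributes `blood` and
#'   `interfaces` (depths of layer tops and the final bottom, m).
#' @export
#' @examples
#' st <- tissue_stack(dplyr::bind_rows(
#'   layer("epidermis", 0.2, 50),
#'   layer("dermis", 1.0, 70, perfused = TRUE),
#'   layer("fat", 1.6, 7, perfused = TRUE)
#' ))
#' interface_depths(st)
tissue_stack <- function(layers, blood = blood_model()) {
  if (!inherits(blood, "blood_model")) {
    abort("`blood` must be a blood_model()")
  }
  layers <- as_tibble(layers)
  if (nrow(layers) < 1) abort("a tissue stack needs at least one layer")
  defaults <- list(mu_s_prime = 0, g = 0, n = 1, rho = 1050, c_p = 3600,
                   k = 0.5, perfused = FALSE)
  for (col in names(defaults)) {
    if (is.null(layers[[col]])) layers[[col]] <- defaults[[col]]
  }
  required <- c("name", "thickness", "mu_a")
  missing <- setdiff(required, names(layers))
  if (length(missing)) {
    abort(paste0("layer table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  layers$name <- as.character(layers$name)
  validate_layers(layers)
  layers <- layers[, c("name", "thickness", "mu_a", "mu_s_prime", "g", "n",
                       "rho", "c_p", "k", "perfused")]
  structure(
    layers,
    blood = blood,
    interfaces = c(0, cumsum(layers$thickness)),
    class = c("tissue_stack", class(tibble())))
}

validate_layers <- function(layers) {
  check_field <- function(ok, field, what) {
    if (!all(ok)) {
      bad <- layers$name[!ok]
      abort(sprintf("invalid `%s` (%s) in layer(s): %s",
                    field, what, paste(bad, collapse = ", ")))
    }
  }
  num_ok <- function(x) is.numeric(x) & is.finite(x)
  check_field(num_ok(layers$thickness) & layers$thickness > 0,
              "thickness", "must be > 0")
  check_field(num_ok(layers$mu_a) & layers$mu_a >= 0, "mu_a", "must be >= 0")
  check_field(num_ok(layers$mu_s_prime) & layers$mu_s_prime >= 0,
              "mu_s_prime", "must be >= 0")
  check_field(num_ok(layers$g) & layers$g >= 0 & layers$g < 1,
              "g", "must lie in [0, 1)")
  check_field(num_ok(layers$n) & layers$n >= 1, "n", "must be >= 1")
  check_field(num_ok(layers$rho) & layers$rho > 0, "rho", "must be > 0")
  check_field(num_ok(layers$c_p) & layers$c_p > 0, "c_p", "must be > 0")
  check_field(num_ok(layers$k) & layers$k > 0, "k", "must be > 0")
  invisible(layers)
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat(sprintf("<tissue_stack> %d layer(s), total depth %.3g mm\n",
              nrow(x), total_depth(x) * 1000))
  NextMethod()
}

#' Interface depths of a stack
#'
#' @param stack A [tissue_stack()].
#' @return Numeric vector of depths (m): 0, then each interface, then the
#'   stack bottom.
#' @export
interface_depths <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  attr(stack, "interfaces")
}

#' Total stack depth (m)
#' @param stack A [tissue_stack()].
#' @export
total_depth <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  tail(interface_depths(stack), 1)
}

#' Blood model attached to a stack
#' @param stack A [tissue_stack()].
#' @export
stack_blood <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  attr(stack, "blood")
}

#' Look up the layer containing a depth
#'
#' Half-open convention: a depth exactly on an interface belongs to the layer
#' below. `z` must satisfy `0 <= z < total_depth(stack)`.
#'
#' @param stack A [tissue_stack()].
#' @param z Depth(s) below the air-tissue interface, m.
#' @return The matching layer row(s) as a tibble.
#' @export
#' @examples
#' st <- tissue_stack(layer("skin", 1, 10))
#' layer_at(st, 0.5e-3)
layer_at <- function(stack, z) {
  stopifnot(inherits(stack, "tissue_stack"))
  idx <- layer_index_at(stack, z)
  tibble::as_tibble(stack)[idx, , drop = FALSE]
}

# integer index variant used by the grid builder
layer_index_at <- function(stack, z) {
  bounds <- interface_depths(stack)
  if (any(z < 0 | z >= tail(bounds, 1))) {
    abort(sprintf("depth out of range: z must lie in [0, %g) m",
                  tail(bounds, 1)))
  }
  findInterval(z, bounds, rightmost.closed = FALSE)
}

# mu_s from the configured reduced coefficient (MC backend)
mu_s_full <- function(stack) stack$mu_s_prime / (1 - stack$g)

#' @export
tidy.tissue_stack <- function(x, ...) {
  out <- as_tibble(x)
  out$z_top <- head(interface_depths(x), -1)
  out$z_bottom <- tail(interface_depths(x), -1)
  out
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number", name))
  }
}
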