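# Layered Beer-Lambert attenuation: the 1D analytical reference model.
# Following the usual analytical treatment of turbid media in this band,
# scattering is folded into absorption, so the attenuation exponent per layer
# is mu_a + mu_s'. For the THz scenarios mu_s' = 0 and this is plain mu_a.

# cumulative optical depth at the layer tops, plus per-layer attenuation
bl_tau_table <- function(stack) {
  mu_t <- stack$mu_a + stack$mu_s_prime
  tops <- head(interface_depths(stack), -1)
  tau_top <- c(0, cumsum(mu_t * stack$thickness))  # length nl + 1
  list(mu_t = mu_t, tops = tops, tau_top = tau_top)
}

#' Layered Beer-Lambert axial intensity profile
#'
#' Normalized intensity `I(z)/I(0) = exp(-sum over traversed layers of
#' (mu_a + mu_s') * path)`: piecewise exponential, continuous at interfaces,
#' and exactly 1 at the surface.
#'
#' @param stack A [tissue_stack()].
#' @param depths Depths at which to evaluate, m; must lie in
#'   `[0, total_depth(stack)]`.
#' @return An `axial_profile` tibble with columns `z` (m) and `value`.
#' @export
#' @examples
#' st <- tissue_stack(layer("epidermis", 0.2, 50))
#' beer_lambert_profile(st, 0.2e-3)$value  # exp(-1)
beer_lambert_profile <- function(stack, depths) {
  stopifnot(inherits(stack, "tissue_stack"))
  L <- total_depth(stack)
  if (any(depths < 0 | depths > L)) {
    abort(sprintf("depths must lie within the stack, [0, %g] m", L))
  }
  tab <- bl_tau_table(stack)
  # depth exactly at the bottom belongs to the last layer for path purposes
  idx <- pmin(findInterval(depths, interface_depths(stack)), nrow(stack))
  tau <- tab$tau_top[idx] + tab$mu_t[idx] * (depths - tab$tops[idx])
  new_axial_profile(tibble(z = depths, value = exp(-tau)),
                    backend = "beer_lambert")
}

new_axial_profile <- function(df, backend) {
  structure(df, backend = backend,
            class = c("axial_profile", class(tibble())))
}

#' Per-layer absorbed fractions under the 1D Beer-Lambert model
#'
#' Fraction of incident power attenuated within each layer:
#' `exp(-tau_top) - exp(-tau_bottom)`. Together with the transmitted
#' remainder `exp(-tau_total)` the fractions sum to one exactly.
#'
#' @param stack A [tissue_stack()].
#' @return Tibble with columns `layer` and `fraction`, one row per layer plus
#'   a final `"(transmitted)"` row.
#' @export
beer_lambert_fractions <- function(stack) {
  stopifnot(inherits(stack, "tissue_stack"))
  tab <- bl_tau_table(stack)
  surv <- exp(-tab$tau_top)
  tibble(
    layer = c(stack$name, "(transmitted)"),
    fraction = c(-diff(surv), tail(surv, 1))
  )
}

#' Absorbed fraction of one named layer (Beer-Lambert)
#'
#' @param stack A [tissue_stack()].
#' @param layer_name Name of a layer in the stack.
#' @return The fraction of incident power attenuated in that layer.
#' @export
#' @examples
#' st <- tissue_stack(layer("epidermis", 0.2, 50))
#' bl_absorbed_fraction(st, "epidermis")  # 1 - exp(-1)
bl_absorbed_fraction <- function(stack, layer_name) {
  fr <- beer_lambert_fractions(stack)
  hit <- match(layer_name, stack$name)
  if (is.na(hit)) {
    abort(sprintf("unknown layer '%s'; stack has: %s", layer_name,
                  paste(stack$name, collapse = ", ")))
  }
  fr$fraction[hit]
}
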