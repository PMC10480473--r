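# Axisymmetric (r, z) finite-volume grid shared by the optics and thermal
# solvers. z = 0 is the air-tissue interface and increases into the tissue;
# axial edges snap to layer interfaces so every cell lies wholly inside one
# layer. Radial cells are uniform annuli out to r_max.

#' Build the shared axisymmetric grid
#'
#' @param stack A [tissue_stack()].
#' @param dr Radial cell size, m.
#' @param dz Requested axial cell size, m. Either a scalar or one value per
#'   layer. Within each layer the actual spacing is `thickness / round(...)`
#'   so cell edges coincide exactly with layer interfaces.
#' @param r_max Radial extent of the domain, m. For beam sources keep
#'   `r_max >= 3 * waist` (checked by the solvers).
#' @return An `axi_grid` list: `r_edges`, `z_edges`, cell centers `r`, `z`,
#'   per-z-cell `layer_index`, annulus areas, volumes.
#' @export
#' @examples
#' st <- tissue_stack(layer("epidermis", 0.2, 50))
#' g <- axi_grid(st, dr = 5e-4, dz = 2e-5, r_max = 0.06)
#' g$nz  # 0.2 mm / 0.02 mm = 10 axial cells
axi_grid <- function(stack, dr, dz, r_max) {
  stopifnot(inherits(stack, "tissue_stack"))
  check_positive(dr, "dr")
  check_positive(r_max, "r_max")
  if (!is.numeric(dz) || any(dz <= 0)) abort("`dz` must be positive")
  nl <- nrow(stack)
  dz <- if (length(dz) == 1) rep(dz, nl) else dz
  if (length(dz) != nl) abort("`dz` must be scalar or one value per layer")

  # axial edges, snapped per layer
  z_edges <- 0
  layer_index <- integer(0)
  tops <- head(interface_depths(stack), -1)
  for (l in seq_len(nl)) {
    th <- stack$thickness[l]
    ncell <- round(th / dz[l])
    if (ncell < 1) {
      abort(sprintf(
        "dz = %g m exceeds the thickness of layer '%s' (%g m); refine dz",
        dz[l], stack$name[l], th))
    }
    z_edges <- c(z_edges, tops[l] + th * seq_len(ncell) / ncell)
    layer_index <- c(layer_index, rep(l, ncell))
  }

  nr <- max(1L, as.integer(ceiling(r_max / dr - 1e-9)))
  r_edges <- seq(0, r_max, length.out = nr + 1)

  g <- list(
    r_edges = r_edges,
    z_edges = z_edges,
    r = (head(r_edges, -1) + tail(r_edges, -1)) / 2,
    z = (head(z_edges, -1) + tail(z_edges, -1)) / 2,
    dr = diff(r_edges),
    dz = diff(z_edges),
    nr = nr,
    nz = length(z_edges) - 1L,
    layer_index = layer_index,
    # annulus cross-section of each radial cell (axial face area, m^2)
    area_z = pi * diff(r_edges^2),
    interfaces = interface_depths(stack)
  )
  class(g) <- "axi_grid"
  g
}

#' @export
print.axi_grid <- function(x, ...) {
  cat(sprintf(
    "<axi_grid> %d x %d cells (r x z), r_max %.3g mm, depth %.3g mm\n",
    x$nr, x$nz, max(x$r_edges) * 1000, max(x$z_edges) * 1000))
  invisible(x)
}

#' Cell volumes of an axisymmetric grid
#'
#' @param grid An [axi_grid()].
#' @return `nr x nz` matrix of cell volumes, m^3 (full 2*pi revolution).
#' @export
cell_volumes <- function(grid) {
  stopifnot(inherits(grid, "axi_grid"))
  outer(grid$area_z, grid$dz)
}

# cells (nr x nz logical) belonging to a given layer index
layer_mask <- function(grid, l) {
  matrix(rep(grid$layer_index == l, each = grid$nr), grid$nr, grid$nz)
}

#' Long-format view of a gridded field
#'
#' @param grid An [axi_grid()].
#' @param ... Named `nr x nz` matrices to include as value columns.
#' @return Tibble with `r`, `z` (cell centers, m) and one column per field.
#' @export
grid_tibble <- function(grid, ...) {
  fields <- list(...)
  out <- tibble(
    r = rep(grid$r, times = grid$nz),
    z = rep(grid$z, each = grid$nr),
    layer = rep(grid$layer_index, each = grid$nr)
  )
  for (nm in names(fields)) out[[nm]] <- as.vector(fields[[nm]])
  out
}
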