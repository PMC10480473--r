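# Steady-state diffusion approximation of the radiative transfer equation on
# the axisymmetric grid:
#
#   -div( D grad Phi ) + mu_a Phi = 0,   Phi(r, 0) = (2P / pi w^2) e^(-2 r^2 / w^2)
#
# The transient 1/v dPhi/dt term is dropped: photon transport equilibrates in
# picoseconds while the coupled thermal problem evolves over seconds, so only
# the stationary fluence matters. Finite-volume 5-point stencil, harmonic
# averaging of D across layer interfaces, sparse direct solve.

#' Settings for the diffusion optics backend
#'
#' @param diffusion_convention `"standard_third"` (default) uses the textbook
#'   diffusion coefficient `D = 1/(3 (mu_a + mu_s'))`, giving the effective
#'   attenuation `sqrt(3 mu_a (mu_a + mu_s'))`. `"paper_literal"` uses
#'   `D = 1/(mu_a + mu_s')`, under which a non-scattering medium decays as
#'   `exp(-mu_a z)`, i.e. coincides with Beer-Lambert on the axis.
#' @param far_boundary Condition at the bottom and outer radius:
#'   `"zero_fluence"` (default; emulates an unbounded absorbing surround) or
#'   `"robin"` (partial-current style, extrapolation length `2 D`).
#' @param v Wave speed in tissue, m/s. Retained for documentation of the
#'   dropped transient term; it does not enter the steady solve.
#' @param solver_tol Relative tolerance for the discrete power-conservation
#'   residual; the solve errors if it is exceeded.
#' @return A `diffusion_settings` list.
#' @export
diffusion_settings <- function(diffusion_convention = c("standard_third",
                                                        "paper_literal"),
                               far_boundary = c("zero_fluence", "robin"),
                               v = 2.998e8 / 1.4,
                               solver_tol = 1e-8) {
  check_positive(solver_tol, "solver_tol")
  structure(
    list(diffusion_convention = match.arg(diffusion_convention),
         far_boundary = match.arg(far_boundary),
         v = v, solver_tol = solver_tol),
    class = "diffusion_settings"
  )
}

diffusion_coefficient <- function(stack, convention) {
  mu_t <- stack$mu_a + stack$mu_s_prime
  if (any(mu_t <= 0)) {
    abort(paste0(
      "diffusion coefficient undefined: mu_a + mu_s' must be > 0 in every ",
      "layer (offending: ",
      paste(stack$name[mu_t <= 0], collapse = ", "), ")"))
  }
  if (convention == "standard_third") 1 / (3 * mu_t) else 1 / mu_t
}

#' Solve the steady-state fluence field
#'
#' Dirichlet Gaussian incidence at z = 0, Neumann symmetry at r = 0, far
#' boundaries per `settings`. Returns the fluence rate, the absorbed power
#' density `q_abs = mu_a * Phi`, and conservation diagnostics. Power entering
#' through the illuminated boundary (`incident_power`, the discrete boundary
#' influx) equals absorbed plus escaped power to within `solver_tol`.
#'
#' @param stack A [tissue_stack()].
#' @param source A [gaussian_source()].
#' @param grid An [axi_grid()] covering the stack.
#' @param settings A [diffusion_settings()].
#' @return A `fluence_field`: grid, `phi` and `q_abs` matrices (nr x nz),
#'   `incident_power` (W), `absorbed_power`, `escaped_fraction`, `residual`.
#' @export
#' @examples
#' st <- tissue_stack(layer("slab", 2, 20))
#' g <- axi_grid(st, dr = 1e-3, dz = 2e-5, r_max = 0.03)
#' f <- solve_fluence(st, gaussian_source(0.1, 0.01), g)
#' glance(f)
solve_fluence <- function(stack, source, grid,
                          settings = diffusion_settings()) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(source, "source_spec"),
            inherits(grid, "axi_grid"))
  check_grid_alignment(grid, stack)
  if (max(grid$r_edges) < 3 * source$waist) {
    warn("grid r_max < 3 * beam waist; far-field truncation may bias totals")
  }

  D <- diffusion_coefficient(stack, settings$diffusion_convention)
  D_cell <- D[grid$layer_index]          # per z-cell (layers are z-wise)
  mu_a_cell <- stack$mu_a[grid$layer_index]

  ops <- assemble_diffusion(grid, D_cell, mu_a_cell, settings$far_boundary)
  phi_bc <- beam_irradiance(source, grid$r)
  b <- numeric(grid$nr * grid$nz)
  b[seq_len(grid$nr)] <- ops$g_top * phi_bc

  phi_vec <- as.numeric(Matrix::solve(ops$A, b))
  phi <- matrix(phi_vec, grid$nr, grid$nz)
  vol <- cell_volumes(grid)
  q_abs <- sweep(phi, 2, mu_a_cell, `*`)

  influx <- sum(ops$g_top * (phi_bc - phi[, 1]))
  escape <- sum(ops$g_bottom * phi[, grid$nz]) + sum(ops$g_side * phi[grid$nr, ])
  absorbed <- sum(q_abs * vol)
  residual <- if (source$power > 0) {
    abs(influx - absorbed - escape) / influx
  } else 0
  if (residual > settings$solver_tol) {
    abort(sprintf(
      "fluence solve failed conservation check: relative residual %.3g > %g",
      residual, settings$solver_tol))
  }

  structure(
    list(grid = grid, stack = stack, source = source, settings = settings,
         phi = phi, q_abs = q_abs,
         incident_power = influx,
         absorbed_power = absorbed,
         escaped_fraction = if (influx > 0) escape / influx else 0,
         residual = residual,
         surface_phi = phi_bc),
    class = "fluence_field"
  )
}

# sparse FV operator for -div(D grad .) + mu_a on the axisymmetric grid;
# returns the matrix plus the boundary conductances used for flux accounting
assemble_diffusion <- function(grid, D_cell, mu_a_cell, far_boundary) {
  nr <- grid$nr; nz <- grid$nz
  idx <- function(i, j) i + (j - 1L) * nr
  vol <- cell_volumes(grid)

  ii <- jj <- xx <- list(); t <- 0
  push <- function(i, j, x) {
    t <<- t + 1; ii[[t]] <<- i; jj[[t]] <<- j; xx[[t]] <<- x
  }
  diag_acc <- as.vector(sweep(vol, 2, mu_a_cell, `*`))  # mu_a V

  # radial faces (same layer left/right, so D is the cell value)
  if (nr > 1) {
    for (j in seq_len(nz)) {
      a_face <- 2 * pi * grid$r_edges[2:nr] * grid$dz[j]
      gcond <- D_cell[j] * a_face / diff(grid$r)
      ki <- idx(seq_len(nr - 1), j); ko <- idx(2:nr, j)
      push(ki, ko, -gcond); push(ko, ki, -gcond)
      diag_acc[ki] <- diag_acc[ki] + gcond
      diag_acc[ko] <- diag_acc[ko] + gcond
    }
  }
  # axial faces (harmonic D across possibly different layers)
  if (nz > 1) {
    for (j in seq_len(nz - 1)) {
      d1 <- grid$dz[j] / 2; d2 <- grid$dz[j + 1] / 2
      gcond <- grid$area_z / (d1 / D_cell[j] + d2 / D_cell[j + 1])
      ku <- idx(seq_len(nr), j); kd <- idx(seq_len(nr), j + 1)
      push(ku, kd, -gcond); push(kd, ku, -gcond)
      diag_acc[ku] <- diag_acc[ku] + gcond
      diag_acc[kd] <- diag_acc[kd] + gcond
    }
  }
  # top Dirichlet (half-cell conductance to the boundary value)
  g_top <- D_cell[1] * grid$area_z / (grid$dz[1] / 2)
  diag_acc[idx(seq_len(nr), 1)] <- diag_acc[idx(seq_len(nr), 1)] + g_top
  # far boundaries
  far_cond <- function(D, area, half) {
    if (far_boundary == "zero_fluence") D * area / half
    else area / (half / D + 2)        # extrapolation length 2 D
  }
  g_bottom <- far_cond(D_cell[nz], grid$area_z, grid$dz[nz] / 2)
  diag_acc[idx(seq_len(nr), nz)] <- diag_acc[idx(seq_len(nr), nz)] + g_bottom
  a_side <- 2 * pi * max(grid$r_edges) * grid$dz
  g_side <- far_cond(D_cell, a_side, grid$dr[nr] / 2)
  diag_acc[idx(nr, seq_len(nz))] <- diag_acc[idx(nr, seq_len(nz))] + g_side

  kk <- seq_len(nr * nz)
  A <- Matrix::sparseMatrix(
    i = c(unlist(ii), kk), j = c(unlist(jj), kk),
    x = c(unlist(xx), diag_acc), dims = c(nr * nz, nr * nz))
  list(A = A, g_top = g_top, g_bottom = g_bottom, g_side = g_side)
}

check_grid_alignment <- function(grid, stack) {
  gi <- grid$interfaces; si <- interface_depths(stack)
  if (length(gi) != length(si) || any(abs(gi - si) > 1e-12)) {
    abort("grid was built for a different stack (layer interfaces differ)")
  }
  invisible(TRUE)
}

#' Per-layer absorbed power fractions of a fluence field
#'
#' Cylindrical-volume integral of `q_abs` over each layer, normalized by the
#' power delivered through the illuminated boundary. Together with the
#' escaped fraction the fractions sum to 1 (within the solver tolerance).
#'
#' @param field A `fluence_field` from [solve_fluence()].
#' @param stack The [tissue_stack()] the field was solved on.
#' @return Tibble with `layer`, `fraction`; the escaped fraction is attached
#'   as attribute `escaped_fraction`.
#' @export
absorbed_fraction_by_layer <- function(field, stack) {
  stopifnot(inherits(field, "fluence_field"))
  check_grid_alignment(field$grid, stack)
  vol <- cell_volumes(field$grid)
  p_layer <- vapply(seq_len(nrow(stack)), function(l) {
    cols <- field$grid$layer_index == l
    sum(field$q_abs[, cols, drop = FALSE] * vol[, cols, drop = FALSE])
  }, numeric(1))
  denom <- field$incident_power
  frac <- if (denom > 0) p_layer / denom else rep(0, length(p_layer))
  structure(tibble(layer = stack$name, fraction = frac),
            escaped_fraction = if (denom > 0) field$escaped_fraction else 0)
}

#' Normalized centerline profile of a fluence field
#'
#' `Phi(0, z) / Phi(0, 0)`: the innermost-ring fluence against depth,
#' normalized to 1 at the illuminated surface (the Dirichlet value there).
#'
#' @param field A `fluence_field`.
#' @return An `axial_profile` tibble (`z`, `value`), starting at `z = 0`
#'   with value 1.
#' @export
centerline_profile <- function(field) {
  UseMethod("centerline_profile")
}

#' @export
centerline_profile.fluence_field <- function(field) {
  phi0 <- field$surface_phi[1]
  if (phi0 <= 0) abort("zero-power source: centerline cannot be normalized")
  new_axial_profile(
    tibble(z = c(0, field$grid$z), value = c(1, field$phi[1, ] / phi0)),
    backend = "diffusion")
}
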