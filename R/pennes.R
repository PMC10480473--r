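# Transient Pennes bioheat solver on the shared axisymmetric grid:
#
#   rho c_p dT/dt = div( k grad T ) + rho_b c_pb omega_b (T_b - T) + Q_met
#                   + q_abs * s(t)
#
# The advective term rho c_p u . grad T is carried with u = 0 (no bulk tissue
# motion; perfusion enters only through the sink term), which is the standard
# Pennes usage. Boundary conditions: convective flux -k dT/dz = h (T - T_amb)
# at z = 0, insulated far boundaries. Because the system is linear, the
# temperature *rise* above the no-source baseline obeys the same operator
# with homogeneous boundary data, so the transient solver integrates the
# rise field directly and the plateau is the stationary solve.

#' Thermal boundary at the skin surface
#'
#' @param h Convection coefficient at z = 0, W/(m^2 K) (>= 0).
#' @param T_ambient Ambient air temperature, K.
#' @return A `thermal_boundary` list (far boundaries are insulated).
#' @export
thermal_boundary <- function(h = 10, T_ambient = 296.15) {
  check_nonneg(h, "h")
  check_positive(T_ambient, "T_ambient")
  structure(list(h = h, T_ambient = T_ambient, outer = "insulated"),
            class = "thermal_boundary")
}

#' Time-stepping controls for the transient solver
#'
#' @param dt Time step, s. Pulsed runs require `dt <= (duty/frequency)/10`
#'   so every ON phase is resolved by at least ten steps.
#' @param t_end Final time, s (>= dt).
#' @param scheme `"backward_euler"` (default) or `"crank_nicolson"`; both
#'   implicit, suitable for the stiff near-surface deposition.
#' @param snapshot_times Times (s) at which to store full temperature-rise
#'   fields.
#' @return A `thermal_settings` list.
#' @export
thermal_settings <- function(dt, t_end, scheme = c("backward_euler",
                                                   "crank_nicolson"),
                             snapshot_times = numeric(0)) {
  check_positive(dt, "dt")
  if (t_end < dt) abort("`t_end` must be >= dt")
  structure(list(dt = dt, t_end = t_end, scheme = match.arg(scheme),
                 snapshot_times = snapshot_times),
            class = "thermal_settings")
}

# Conduction + perfusion + convection operator K (SPD, W/K units) and the
# capacity diagonal M = rho c_p V. Returns sparse K, M vector, and the
# pieces needed for right-hand sides and energy audits.
assemble_pennes <- function(stack, grid, boundary) {
  nr <- grid$nr; nz <- grid$nz
  idx <- function(i, j) i + (j - 1L) * nr
  vol <- cell_volumes(grid)
  blood <- stack_blood(stack)
  k_cell <- stack$k[grid$layer_index]
  rho_c <- (stack$rho * stack$c_p)[grid$layer_index]
  perf_coef <- blood$rho_b * blood$c_pb * blood$omega_b *
    as.numeric(stack$perfused)[grid$layer_index]      # W/(m^3 K), per z-cell

  ii <- jj <- xx <- list(); t <- 0
  push <- function(i, j, x) {
    t <<- t + 1; ii[[t]] <<- i; jj[[t]] <<- j; xx[[t]] <<- x
  }
  perf_diag <- as.vector(sweep(vol, 2, perf_coef, `*`))
  diag_acc <- perf_diag

  if (nr > 1) {
    for (j in seq_len(nz)) {
      a_face <- 2 * pi * grid$r_edges[2:nr] * grid$dz[j]
      gcond <- k_cell[j] * a_face / diff(grid$r)
      ki <- idx(seq_len(nr - 1), j); ko <- idx(2:nr, j)
      push(ki, ko, -gcond); push(ko, ki, -gcond)
      diag_acc[ki] <- diag_acc[ki] + gcond
      diag_acc[ko] <- diag_acc[ko] + gcond
    }
  }
  if (nz > 1) {
    for (j in seq_len(nz - 1)) {
      d1 <- grid$dz[j] / 2; d2 <- grid$dz[j + 1] / 2
      gcond <- grid$area_z / (d1 / k_cell[j] + d2 / k_cell[j + 1])
      ku <- idx(seq_len(nr), j); kd <- idx(seq_len(nr), j + 1)
      push(ku, kd, -gcond); push(kd, ku, -gcond)
      diag_acc[ku] <- diag_acc[ku] + gcond
      diag_acc[kd] <- diag_acc[kd] + gcond
    }
  }
  # convective top: conduction through the half cell in series with the film
  g_conv <- if (boundary$h > 0) {
    grid$area_z / (grid$dz[1] / (2 * k_cell[1]) + 1 / boundary$h)
  } else {
    rep(0, nr)
  }
  diag_acc[idx(seq_len(nr), 1)] <- diag_acc[idx(seq_len(nr), 1)] + g_conv

  kk <- seq_len(nr * nz)
  K <- Matrix::sparseMatrix(
    i = c(unlist(ii), kk), j = c(unlist(jj), kk),
    x = c(unlist(xx), diag_acc), dims = c(nr * nz, nr * nz))
  list(K = K, M = as.vector(sweep(vol, 2, rho_c, `*`)),
       perf_diag = perf_diag, g_conv = g_conv, vol = vol)
}

#' Steady no-source baseline temperature field
#'
#' Solves `div(k grad T) + rho_b c_pb omega_b (T_b - T) + Q_met = 0` with the
#' convective top flux and insulated far boundaries. This is the reference
#' field all reported temperature rises are measured against; convection
#' makes it non-uniform (slightly cooler at the surface than the arterial
#' blood).
#'
#' @param stack A [tissue_stack()] with thermal properties on every layer.
#' @param grid An [axi_grid()].
#' @param boundary A [thermal_boundary()].
#' @return A `baseline_field`: the `nr x nz` temperature matrix (K) plus the
#'   assembled operator, reused by the transient solver.
#' @export
#' @examples
#' st <- tissue_stack(layer("skin", 1, 10, perfused = TRUE))
#' g <- axi_grid(st, dr = 2e-3, dz = 1e-4, r_max = 0.02)
#' b <- solve_baseline(st, g, thermal_boundary(h = 0))
#' range(b$T)  # == blood temperature when h = 0, Q_met = 0 balance
solve_baseline <- function(stack, grid, boundary) {
  stopifnot(inherits(stack, "tissue_stack"), inherits(grid, "axi_grid"),
            inherits(boundary, "thermal_boundary"))
  check_grid_alignment(grid, stack)
  blood <- stack_blood(stack)
  any_perf <- any(stack$perfused) && blood$omega_b > 0
  if (boundary$h == 0 && !any_perf) {
    abort(paste0(
      "steady state is unbounded: no heat sink (h = 0 and no perfused ",
      "layer); any metabolic heat would grow without limit"))
  }
  ops <- assemble_pennes(stack, grid, boundary)
  b <- ops$perf_diag * blood$T_b + blood$q_met * as.vector(ops$vol)
  b[seq_len(grid$nr)] <- b[seq_len(grid$nr)] + ops$g_conv * boundary$T_ambient
  Tvec <- as.numeric(Matrix::solve(ops$K, b))
  structure(
    list(T = matrix(Tvec, grid$nr, grid$nz), grid = grid, stack = stack,
         boundary = boundary, ops = ops),
    class = "baseline_field"
  )
}

validate_q_abs <- function(q_abs, grid) {
  if (!is.matrix(q_abs) || nrow(q_abs) != grid$nr || ncol(q_abs) != grid$nz) {
    abort(sprintf("`q_abs` must be an %d x %d matrix on the thermal grid",
                  grid$nr, grid$nz))
  }
  if (any(!is.finite(q_abs)) || any(q_abs < 0)) {
    abort("`q_abs` must be finite and non-negative")
  }
  invisible(q_abs)
}

#' Transient temperature rise under an absorbed-power source
#'
#' Implicit time integration of the rise field from the baseline, with the
#' source `q_abs * s(t)` modulated by the square-wave pulse schedule
#' (`s == 1` for continuous exposure). Steps are subdivided at pulse
#' switching instants so the signal is piecewise-constant per step.
#'
#' @param stack,grid,boundary As in [solve_baseline()].
#' @param q_abs Absorbed power density, W/m^3, `nr x nz` matrix on `grid`
#'   (from a fluence field via [absorbed_power_density()], or any source).
#' @param schedule A [pulse_schedule()] or `NULL` for continuous.
#' @param settings A [thermal_settings()].
#' @return A `temperature_result`: tibble `series` (`t`, `T_max_rise`, K),
#'   snapshot fields, the final rise field, and the baseline.
#' @export
solve_transient <- function(stack, grid, boundary, q_abs, schedule = NULL,
                            settings) {
  stopifnot(inherits(settings, "thermal_settings"))
  validate_q_abs(q_abs, grid)
  if (!is_continuous(schedule)) {
    on_time <- schedule$duty_cycle / schedule$frequency
    if (settings$dt > on_time / 10 + 1e-12) {
      abort(sprintf(
        "pulsed run needs dt <= (duty/frequency)/10 = %g s (got %g s)",
        on_time / 10, settings$dt))
    }
  }
  baseline <- solve_baseline(stack, grid, boundary)
  ops <- baseline$ops
  qv <- as.vector(q_abs) * as.vector(ops$vol)   # W per cell

  n <- grid$nr * grid$nz
  theta <- numeric(n)                            # rise field, K
  t_now <- 0
  times <- 0
  max_rise <- 0
  snapshots <- list()
  snap_due <- sort(settings$snapshot_times)

  solver_cache <- new.env(parent = emptyenv())
  step_solver <- function(dt) {
    key <- sprintf("%.15g", dt)
    if (is.null(solver_cache[[key]])) {
      lhs <- ops$K
      Matrix::diag(lhs) <- Matrix::diag(lhs) + ops$M / dt
      if (settings$scheme == "crank_nicolson") {
        lhs <- ops$K / 2
        Matrix::diag(lhs) <- Matrix::diag(ops$K) / 2 + ops$M / dt
      }
      solver_cache[[key]] <- Matrix::Cholesky(
        Matrix::forceSymmetric(lhs), LDL = FALSE)
    }
    solver_cache[[key]]
  }

  switch_times <- if (is_continuous(schedule)) {
    settings$t_end + 1
  } else {
    period <- 1 / schedule$frequency
    on <- schedule$duty_cycle * period
    k <- seq_len(ceiling(settings$t_end / period) + 1) - 1
    sort(unique(c(k * period, k * period + on)))
  }

  while (t_now < settings$t_end - 1e-12) {
    next_switch <- min(switch_times[switch_times > t_now + 1e-12],
                       settings$t_end + 1)
    dt <- min(settings$dt, next_switch - t_now, settings$t_end - t_now)
    s <- pulse_signal(schedule, t_now + dt / 2)
    fac <- step_solver(dt)
    rhs <- ops$M / dt * theta + s * qv
    if (settings$scheme == "crank_nicolson") {
      rhs <- ops$M / dt * theta -
        as.numeric(ops$K %*% theta) / 2 + s * qv
    }
    theta <- as.numeric(Matrix::solve(fac, rhs))
    if (any(!is.finite(theta))) {
      abort(sprintf("non-finite temperature field at t = %g s", t_now + dt))
    }
    t_now <- t_now + dt
    times <- c(times, t_now)
    max_rise <- c(max_rise, max(theta))
    while (length(snap_due) && snap_due[1] <= t_now + 1e-12) {
      snapshots[[sprintf("t=%gs", snap_due[1])]] <-
        matrix(theta, grid$nr, grid$nz)
      snap_due <- snap_due[-1]
    }
  }

  structure(
    list(series = tibble(t = times, T_max_rise = max_rise),
         snapshots = snapshots,
         final_rise = matrix(theta, grid$nr, grid$nz),
         baseline = baseline$T, grid = grid, schedule = schedule,
         settings = settings),
    class = "temperature_result"
  )
}

#' @export
print.temperature_result <- function(x, ...) {
  cat(sprintf(
    "<temperature_result> %d steps to t = %g s; final max rise %.4g K\n",
    nrow(x$series) - 1, max(x$series$t), tail(x$series$T_max_rise, 1)))
  invisible(x)
}

#' Plateau (asymptotic) maximum rise of a transient run
#'
#' Checks that the late-time slope of the max-rise series (for pulsed runs,
#' of its per-cycle maximum envelope) is below `tol` and returns the plateau
#' value, with the variation over the last decade of the run attached as
#' attribute `"last_decade_range"`.
#'
#' @param result A `temperature_result`.
#' @param tol Convergence tolerance on `|d T_max / dt|`, K/s.
#' @return Plateau maximum rise, K.
#' @export
steady_max_rise <- function(result, tol = 1e-4) {
  stopifnot(inherits(result, "temperature_result"))
  series <- result$series
  if (!is_continuous(result$schedule)) {
    period <- 1 / result$schedule$frequency
    cyc <- floor(series$t / period * (1 - 1e-12))
    series <- dplyr::summarise(
      dplyr::group_by(series, cycle = cyc),
      t = max(.data$t), T_max_rise = max(.data$T_max_rise), .groups = "drop")
  }
  t_end <- max(series$t)
  late <- series[series$t >= 0.9 * t_end, , drop = FALSE]
  if (nrow(late) < 2) abort("too few late-time samples; extend t_end")
  slope <- coef(lm(T_max_rise ~ t, data = late))[["t"]]
  if (!is.finite(slope) || abs(slope) > tol) {
    abort(sprintf(
      "max rise still changing at %.3g K/s (> %g); run longer (t_end)",
      slope, tol))
  }
  dec <- series[series$t >= 0.9 * t_end, ]
  structure(tail(series$T_max_rise, 1),
            last_decade_range = diff(range(dec$T_max_rise)))
}

#' Stationary temperature rise (direct plateau solve)
#'
#' The Pennes operator is linear, so the asymptote of the implicit transient
#' scheme is the solution of `K theta = duty * q_abs V`. This gives sweep
#' drivers and acceptance checks the plateau at one sparse solve.
#'
#' @param stack,grid,boundary As in [solve_baseline()].
#' @param q_abs Absorbed power density matrix, W/m^3.
#' @param duty Scaling of the time-averaged source (duty cycle), in `(0, 1]`.
#' @return A `plateau_field`: max rise `max_rise` (K) and the full rise
#'   matrix `rise`.
#' @export
plateau_rise <- function(stack, grid, boundary, q_abs, duty = 1) {
  validate_q_abs(q_abs, grid)
  if (duty <= 0 || duty > 1) abort("`duty` must lie in (0, 1]")
  baseline <- solve_baseline(stack, grid, boundary)
  ops <- baseline$ops
  theta <- as.numeric(Matrix::solve(
    ops$K, duty * as.vector(q_abs) * as.vector(ops$vol)))
  structure(
    list(max_rise = max(theta), rise = matrix(theta, grid$nr, grid$nz),
         grid = grid, duty = duty, baseline = baseline$T),
    class = "plateau_field"
  )
}

#' Asymptotic per-cycle maximum rise of a pulsed exposure
#'
#' Integrates the periodic orbit directly: starts from the duty-scaled
#' stationary field (the cycle-averaged asymptote) and steps a handful of
#' pulse cycles at fine resolution until consecutive per-cycle maxima agree,
#' then reports the converged per-cycle maximum.
#'
#' @param stack,grid,boundary As in [solve_baseline()].
#' @param q_abs Absorbed power density matrix, W/m^3 (unmodulated).
#' @param schedule A [pulse_schedule()].
#' @param n_cycles Maximum cycles to integrate.
#' @param rel_tol Relative agreement between consecutive cycle maxima.
#' @return Per-cycle maximum plateau rise, K, with attribute `"cycles_run"`.
#' @export
pulsed_plateau_rise <- function(stack, grid, boundary, q_abs, schedule,
                                n_cycles = 20, rel_tol = 1e-3) {
  stopifnot(inherits(schedule, "pulse_schedule"))
  if (is_continuous(schedule)) {
    return(plateau_rise(stack, grid, boundary, q_abs)$max_rise)
  }
  validate_q_abs(q_abs, grid)
  baseline <- solve_baseline(stack, grid, boundary)
  ops <- baseline$ops
  qv <- as.vector(q_abs) * as.vector(ops$vol)
  period <- 1 / schedule$frequency
  dt <- schedule$duty_cycle * period / 10
  # start on the cycle-averaged asymptote
  theta <- as.numeric(Matrix::solve(ops$K, schedule$duty_cycle * qv))

  lhs <- ops$K
  Matrix::diag(lhs) <- Matrix::diag(lhs) + ops$M / dt
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(lhs), LDL = FALSE)

  prev_max <- -Inf; cyc_max <- NA_real_; used <- 0
  for (cyc in seq_len(n_cycles)) {
    cyc_max <- -Inf
    t0 <- (cyc - 1) * period
    nsteps <- max(1L, round(period / dt))
    for (step in seq_len(nsteps)) {
      s <- pulse_signal(schedule, t0 + (step - 0.5) * dt)
      theta <- as.numeric(Matrix::solve(fac, ops$M / dt * theta + s * qv))
      cyc_max <- max(cyc_max, max(theta))
    }
    used <- cyc
    if (is.finite(prev_max) &&
        abs(cyc_max - prev_max) <= rel_tol * abs(cyc_max)) break
    prev_max <- cyc_max
  }
  structure(cyc_max, cycles_run = used)
}
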