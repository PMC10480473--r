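# Pennes bioheat solver: baseline closed forms, transient behaviour,
# pulse modulation.

test_that("pulse signal follows the schedule and its continuous limit", {
  s <- pulse_schedule(0.5, 1)
  expect_equal(pulse_signal(s, c(0, 0.25, 0.499, 0.5, 0.75, 0.999, 1.0)),
               c(1, 1, 1, 0, 0, 0, 1))
  s100 <- pulse_schedule(0.5, 100)
  expect_equal(pulse_signal(s100, c(0.002, 0.007)), c(1, 0))
  expect_equal(pulse_signal(pulse_schedule(1, 5), seq(0, 2, 0.3)),
               rep(1, 7))
  expect_equal(pulse_signal(NULL, 3.2), 1)
  expect_error(pulse_schedule(0, 1), "\\(0, 1\\]")
})

test_that("baseline equals blood temperature when nothing drives gradients", {
  st <- slab_stack(perfused = TRUE)
  blood0 <- blood_model(q_met = 0)
  attr(st, "blood") <- blood0
  g <- coarse_grid(st, dz = 2e-4)
  b <- solve_baseline(st, g, thermal_boundary(h = 0))
  expect_equal(max(abs(b$T - blood0$T_b)), 0, tolerance = 1e-10)
})

test_that("insulated, uniformly perfused baseline balances metabolic heat", {
  blood <- blood_model(q_met = 800)
  st <- tissue_stack(layer("slab", 4, 20, perfused = TRUE), blood)
  g <- coarse_grid(st, dz = 2e-4)
  b <- solve_baseline(st, g, thermal_boundary(h = 0))
  expected <- blood$T_b + blood$q_met / (blood$rho_b * blood$c_pb *
                                           blood$omega_b)
  expect_equal(as.vector(b$T), rep(expected, length(b$T)),
               tolerance = 1e-10)
})

test_that("with convection the surface sits between ambient and blood", {
  st <- slab_stack(perfused = TRUE)
  g <- coarse_grid(st, dz = 2e-4)
  bnd <- thermal_boundary(h = 25, T_ambient = 290)
  b <- solve_baseline(st, g, bnd)
  expect_true(all(b$T > bnd$T_ambient))
  expect_true(all(b$T < stack_blood(st)$T_b +
                    stack_blood(st)$q_met))  # loose upper cap
  expect_lt(b$T[1, 1], b$T[1, g$nz])  # cooler at the surface
})

test_that("an unbounded steady state is refused", {
  blood <- blood_model(omega_b = 0)
  st <- tissue_stack(layer("slab", 4, 20), blood)
  g <- coarse_grid(st, dz = 2e-4)
  expect_error(solve_baseline(st, g, thermal_boundary(h = 0)), "unbounded")
})

test_that("zero source keeps the rise identically zero", {
  st <- slab_stack(perfused = TRUE)
  g <- coarse_grid(st, dz = 2e-4)
  q0 <- matrix(0, g$nr, g$nz)
  tr <- solve_transient(st, g, thermal_boundary(), q0,
                        settings = thermal_settings(dt = 5, t_end = 50))
  expect_equal(tr$series$T_max_rise, rep(0, nrow(tr$series)))
  expect_equal(steady_max_rise(tr, tol = 1e-8), 0, ignore_attr = TRUE)
})

test_that("rise is linear in the source and transient approaches the plateau", {
  st <- thz_skin_stack()
  g <- axi_grid(st, dr = 2e-3, dz = c(4e-5, 1e-4, 2e-4), r_max = 0.06)
  src <- gaussian_source(0.1, 0.02)
  f <- solve_fluence(st, src, g)
  q <- absorbed_power_density(f)
  bnd <- thermal_boundary()
  p1 <- plateau_rise(st, g, bnd, q)
  p2 <- plateau_rise(st, g, bnd, 2 * q)
  expect_equal(p2$max_rise / p1$max_rise, 2, tolerance = 1e-3)
  tr <- solve_transient(st, g, bnd, q,
                        settings = thermal_settings(dt = 5, t_end = 4000))
  expect_true(all(diff(tr$series$T_max_rise) >= -1e-12))  # monotone rise
  expect_equal(steady_max_rise(tr, tol = 1e-4), p1$max_rise,
               tolerance = 0.01, ignore_attr = TRUE)
  # halving dt barely moves the endpoint (implicit scheme)
  tr2 <- solve_transient(st, g, bnd, q,
                         settings = thermal_settings(dt = 2.5, t_end = 4000))
  expect_equal(tail(tr2$series$T_max_rise, 1),
               tail(tr$series$T_max_rise, 1), tolerance = 5e-3)
})

test_that("crank-nicolson and backward euler agree at the plateau", {
  st <- slab_stack(perfused = TRUE)
  g <- coarse_grid(st, dz = 2e-4)
  q <- matrix(5e4, g$nr, g$nz)
  be <- solve_transient(st, g, thermal_boundary(), q,
                        settings = thermal_settings(dt = 10, t_end = 3000))
  cn <- solve_transient(st, g, thermal_boundary(), q,
                        settings = thermal_settings(dt = 10, t_end = 3000,
                                                    scheme = "crank_nicolson"))
  expect_equal(tail(be$series$T_max_rise, 1), tail(cn$series$T_max_rise, 1),
               tolerance = 1e-3)
})

test_that("a too-coarse time step for the pulse schedule is refused", {
  st <- slab_stack(perfused = TRUE)
  g <- coarse_grid(st, dz = 2e-4)
  q <- matrix(1e4, g$nr, g$nz)
  expect_error(
    solve_transient(st, g, thermal_boundary(), q,
                    schedule = pulse_schedule(0.5, 10),
                    settings = thermal_settings(dt = 0.05, t_end = 1)),
    "dt <=")
})

test_that("an unconverged run is flagged rather than reported", {
  st <- slab_stack(perfused = TRUE)
  g <- coarse_grid(st, dz = 2e-4)
  q <- matrix(5e4, g$nr, g$nz)
  tr <- solve_transient(st, g, thermal_boundary(), q,
                        settings = thermal_settings(dt = 2, t_end = 30))
  expect_error(steady_max_rise(tr, tol = 1e-6), "run longer")
})

test_that("pulsed plateau tracks duty cycle and stays frequency-invariant", {
  st <- thz_skin_stack()
  g <- axi_grid(st, dr = 2e-3, dz = c(4e-5, 1e-4, 2e-4), r_max = 0.06)
  f <- solve_fluence(st, gaussian_source(0.5, 0.02), g)
  q <- absorbed_power_density(f)
  bnd <- thermal_boundary()
  cont <- plateau_rise(st, g, bnd, q)$max_rise
  ratios <- vapply(c(1, 10, 100), function(fr) {
    as.numeric(pulsed_plateau_rise(st, g, bnd, q,
                                   pulse_schedule(0.5, fr))) / cont
  }, numeric(1))
  expect_true(all(abs(ratios - 0.5) < 0.05))
  expect_lt(diff(range(ratios)), 0.05)
  quarter <- as.numeric(pulsed_plateau_rise(st, g, bnd, q,
                                            pulse_schedule(0.25, 10)))
  expect_equal(quarter / cont, 0.25, tolerance = 0.05)
})
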