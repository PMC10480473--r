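# Steady diffusion-approximation solver.

test_that("homogeneous centerline follows exp(-sqrt(3) mu_a z) within 1%", {
  mu_a <- 2000
  st <- slab_stack(mu_a_cm = mu_a / 100, thickness_mm = 4)
  g <- axi_grid(st, dr = 2e-3, dz = 1 / (50 * mu_a), r_max = 0.12)
  f <- solve_fluence(st, gaussian_source(0.1, 0.04), g)
  cp <- centerline_profile(f)
  mueff <- sqrt(3) * mu_a
  sel <- cp$z > 0 & cp$z <= 3 / mueff
  expect_lt(max(abs(cp$value[sel] / exp(-mueff * cp$z[sel]) - 1)), 0.01)
  expect_equal(cp$value[1], 1)
  expect_true(all(diff(cp$value) <= 1e-12))   # maximum principle
})

test_that("paper_literal convention reduces to Beer-Lambert on the axis", {
  mu_a <- 3000
  st <- slab_stack(mu_a_cm = mu_a / 100, thickness_mm = 3)
  g <- axi_grid(st, dr = 2e-3, dz = 1 / (60 * mu_a), r_max = 0.12)
  f <- solve_fluence(st, gaussian_source(0.1, 0.04), g,
                     diffusion_settings("paper_literal"))
  cp <- centerline_profile(f)
  sel <- cp$z > 0 & cp$z <= 3 / mu_a
  expect_lt(max(abs(cp$value[sel] / exp(-mu_a * cp$z[sel]) - 1)), 0.01)
})

test_that("scaling the source power scales the field exactly", {
  st <- thz_skin_stack()
  g <- axi_grid(st, dr = 2e-3, dz = c(2e-5, 5e-5, 1e-4), r_max = 0.06)
  f1 <- solve_fluence(st, gaussian_source(0.05, 0.02), g)
  f2 <- solve_fluence(st, gaussian_source(0.15, 0.02), g)
  expect_lt(max(abs(f2$phi / f1$phi - 3)), 1e-10)
  expect_lt(abs(f2$absorbed_power / f1$absorbed_power - 3), 1e-10)
})

test_that("absorbed + escaped power equals the boundary influx", {
  st <- synth_stack(5, n_layers = 2, mu_a_range = c(500, 3000))
  g <- axi_grid(st, dr = 1e-3, dz = 2e-5, r_max = 0.03)
  f <- solve_fluence(st, gaussian_source(0.2, 0.008), g)
  expect_lt(f$residual, 1e-10)
  fr <- absorbed_fraction_by_layer(f, st)
  expect_equal(sum(fr$fraction) + attr(fr, "escaped_fraction"), 1,
               tolerance = 1e-6)
})

test_that("130 GHz layer split: ~80% epidermis, negligible fat", {
  cfg <- scenario("thz_130ghz")
  st <- config_stack(cfg)
  f <- solve_fluence(st, config_source(cfg), config_grid(cfg))
  fr <- absorbed_fraction_by_layer(f, st)
  expect_equal(fr$fraction[1], 1 - exp(-sqrt(3) * 5000 * 2e-4),
               tolerance = 0.01)
  expect_lt(fr$fraction[3], 1e-3)   # bounded by e^-1.73 * e^-12.1 attenuation
})

test_that("zero-power source yields zero fractions and unnormalizable profile", {
  st <- thz_skin_stack()
  g <- axi_grid(st, dr = 2e-3, dz = c(2e-5, 1e-4, 2e-4), r_max = 0.06)
  f <- solve_fluence(st, gaussian_source(0, 0.02), g)
  fr <- absorbed_fraction_by_layer(f, st)
  expect_equal(fr$fraction, rep(0, 3))
  expect_error(centerline_profile(f), "zero-power")
})

test_that("degenerate media and misaligned grids are rejected", {
  clear <- tissue_stack(layer("clear", 1, 0))
  g <- axi_grid(clear, dr = 1e-3, dz = 1e-4, r_max = 0.01)
  expect_error(solve_fluence(clear, gaussian_source(0.1, 0.003), g),
               "undefined")
  st <- thz_skin_stack()
  g2 <- axi_grid(st, dr = 1e-3, dz = c(2e-5, 1e-4, 2e-4), r_max = 0.06)
  other <- slab_stack()
  expect_error(absorbed_fraction_by_layer(
    solve_fluence(st, gaussian_source(0.1, 0.02), g2), other),
    "different stack")
})

test_that("robin far boundary changes little when the medium is deep", {
  st <- slab_stack(mu_a_cm = 30, thickness_mm = 3)
  g <- axi_grid(st, dr = 2e-3, dz = 1e-5, r_max = 0.06)
  src <- gaussian_source(0.1, 0.02)
  f0 <- solve_fluence(st, src, g, diffusion_settings(far_boundary = "zero_fluence"))
  f1 <- solve_fluence(st, src, g, diffusion_settings(far_boundary = "robin"))
  expect_equal(f0$absorbed_power / f0$incident_power,
               f1$absorbed_power / f1$incident_power, tolerance = 1e-3)
})
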