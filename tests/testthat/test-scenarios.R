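# Packaged fixtures, sweep drivers, synthetic stacks.

test_that("fixtures carry the published scenario parameters", {
  st130 <- config_stack(scenario("thz_130ghz"))
  expect_equal(st130$mu_a, c(5000, 7000, 700))
  expect_equal(st130$thickness, c(0.2e-3, 1e-3, 1.6e-3))
  st1t <- config_stack(scenario("thz_1thz"))
  expect_equal(st1t$mu_a, c(13700, 14000, 2500))
  nir <- scenario("nir_1030nm")
  expect_equal(config_source(nir)$waist, 5e-3)
  expect_true(all(config_stack(nir)$mu_s_prime > 0))
  expect_equal(config_stack(nir)$g, rep(0.9, 3))
  bacon <- scenario("bacon")
  expect_equal(config_source(bacon)$power, 0.02)
  expect_equal(stack_blood(config_stack(bacon))$omega_b, 0)
  expect_error(scenario("steak"), "choices")
})

test_that("every fixture round-trips through the config format losslessly", {
  for (nm in c("thz_130ghz", "thz_1thz", "nir_1030nm", "bacon")) {
    cfg <- scenario(nm)
    tmp <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(cfg, tmp)
    back <- read_scenario(tmp)
    a <- unclass(cfg); b <- unclass(back)
    a$.path <- b$.path <- NULL
    expect_identical(a, b, label = nm)
  }
})

test_that("synthetic stacks are reproducible and honour their ranges", {
  a <- synth_stack(21, n_layers = 5, mu_a_range = c(300, 800))
  b <- synth_stack(21, n_layers = 5, mu_a_range = c(300, 800))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$mu_a >= 300 & a$mu_a <= 800))
  one <- synth_stack(1, n_layers = 1)
  expect_equal(nrow(one), 1)
  expect_error(synth_stack(1, mu_a_range = c(5, 1)), "ordered range")
})

test_that("power sweep scales linearly and preserves order/duplicates", {
  cfg <- coarse_config()
  tab <- power_sweep(cfg, c(0.01, 0.05, 0.1, 0.05))
  expect_equal(tab$power, c(0.01, 0.05, 0.1, 0.05))
  expect_equal(tab$plateau_rise / tab$plateau_rise[1],
               c(1, 5, 10, 5), tolerance = 1e-3)
  expect_identical(tab$plateau_rise[2], tab$plateau_rise[4])
  expect_equal(nrow(power_sweep(cfg, numeric(0))), 0)
})

test_that("waist sweep decreases monotonically, sub-quadratically", {
  cfg <- coarse_config()
  tab <- waist_sweep(cfg, c(0.02, 0.03, 0.04))
  expect_true(all(diff(tab$plateau_rise) < 0))
  ratio <- tab$plateau_rise[1] / tab$plateau_rise[3]   # waist doubled
  expect_gt(ratio, 1)
  expect_lt(ratio, 4)
  single <- waist_sweep(cfg, 0.02)
  expect_equal(single$plateau_rise, tab$plateau_rise[1])
})

test_that("duty sweep: duty 1 equals continuous, 0.5 halves it", {
  cfg <- coarse_config()
  cont <- duty_cycle_sweep(cfg, 1)
  direct <- power_sweep(cfg, cfg$source$power_W)
  expect_equal(cont$plateau_rise, direct$plateau_rise, tolerance = 1e-12)
  half <- duty_cycle_sweep(cfg, 0.5, frequencies = c(1, 10))
  expect_equal(half$plateau_rise / cont$plateau_rise,
               rep(0.5, 2), tolerance = 0.05)
  expect_lt(abs(diff(half$plateau_rise)) / cont$plateau_rise, 0.05)
})
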