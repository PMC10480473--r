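# End-to-end coupled runs, exports, manifest replay, backend comparison.

test_that("a coupled run produces outputs, a complete manifest, and replays", {
  # write the coarsened config to disk so the manifest points at the exact
  # parameters that were run
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(coarse_config(), cfg_file)
  cfg <- read_scenario(cfg_file)
  out1 <- withr::local_tempdir()
  res <- run_scenario(cfg, backend = "beer_lambert", out_dir = out1)
  expect_s3_class(res, "scenario_result")
  man <- jsonlite::read_json(file.path(out1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_true(all(file.exists(file.path(out1, man$outputs))))
  expect_equal(man$backend, "beer_lambert")
  expect_equal(man$config_md5, unname(tools::md5sum(cfg$.path)))

  # byte-identical determinism of all numeric outputs
  out2 <- withr::local_tempdir()
  run_scenario(cfg, backend = "beer_lambert", out_dir = out2)
  for (f in man$outputs) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }

  # manifest-driven replay reproduces the numbers
  out3 <- withr::local_tempdir()
  replay_run(file.path(out1, "manifest.json"), out_dir = out3)
  expect_identical(readLines(file.path(out1, "temperature.csv")),
                   readLines(file.path(out3, "temperature.csv")))
})

test_that("exported CSVs conform to their documented schemas", {
  cfg <- coarse_config()
  out <- withr::local_tempdir()
  run_scenario(cfg, backend = "diffusion", out_dir = out)
  fluence <- readr::read_csv(file.path(out, "fluence.csv"),
                             show_col_types = FALSE)
  expect_named(fluence, c("r", "z", "layer", "phi", "q_abs"))
  centerline <- readr::read_csv(file.path(out, "centerline.csv"),
                                show_col_types = FALSE)
  expect_named(centerline, c("depth_m", "normalized_intensity"))
  expect_equal(centerline$normalized_intensity[1], 1)
  temperature <- readr::read_csv(file.path(out, "temperature.csv"),
                                 show_col_types = FALSE)
  expect_named(temperature, c("t_s", "T_max_rise_K"))
  expect_equal(temperature$T_max_rise_K[1], 0)
})

test_that("backends agree on where the power goes in the heat source", {
  cfg <- coarse_config()
  st <- config_stack(cfg); g <- config_grid(cfg); src <- config_source(cfg)
  vol <- cell_volumes(g)
  res_d <- run_scenario(cfg, backend = "diffusion", optics_only = TRUE)
  res_b <- run_scenario(cfg, backend = "beer_lambert", optics_only = TRUE)
  # both deposit (nearly) the whole beam power in this opaque medium
  expect_equal(sum(res_d$q_abs * vol), src$power, tolerance = 1e-3)
  expect_equal(sum(res_b$q_abs * vol), src$power, tolerance = 1e-3)
  expect_error(run_scenario(cfg, backend = "raytrace"))
})

test_that("three-backend comparison reproduces the sub-THz centerline facts", {
  cfg <- scenario("thz_1thz")
  cfg$grid$dr_mm <- 2
  cmp <- compare_optics(cfg, n_photons = 4e4, seed = 2)
  expect_named(cmp, c("z", "beer_lambert", "diffusion", "montecarlo",
                      "mc_stderr"))
  expect_true(all(diff(cmp$beer_lambert) < 0))
  expect_true(all(diff(cmp$diffusion) < 1e-12))
  # by the bottom of the epidermis every backend is below 0.1
  at02 <- cmp[which.min(abs(cmp$z - 0.2e-3)), ]
  expect_lt(at02$beer_lambert, 0.1)    # e^-2.74
  expect_lt(at02$diffusion, 0.1)       # e^-4.75
  expect_lt(at02$montecarlo, 0.1)
})

test_that("the NIR comparison shows an MC subsurface peak, diffusion monotone", {
  cfg <- scenario("nir_1030nm")
  cfg$grid$dr_mm <- 1
  cmp <- compare_optics(cfg, n_photons = 5e4, seed = 4)
  pk <- which.max(cmp$montecarlo)
  expect_gt(pk, 1)                          # maximum is below the surface
  expect_lt(cmp$z[pk], 1e-3)
  expect_true(all(diff(cmp$diffusion) < 1e-12))
})
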