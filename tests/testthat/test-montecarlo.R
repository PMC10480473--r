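# Monte Carlo transport: primitives, conservation, agreement with closed
# forms, reproducibility.

test_that("Henyey-Greenstein sampler has the right limits and mean", {
  expect_equal(sample_henyey_greenstein(0, 0.75), 0.5)
  expect_equal(sample_henyey_greenstein(0, 0), -1)
  u <- withr::with_seed(42, stats::runif(1e6))
  for (g in c(0.3, 0.9)) {
    ct <- sample_henyey_greenstein(g, u)
    expect_true(all(abs(ct) <= 1))
    # <cos theta> = g; variance of HG is (1 - g^2) scale, 3 sigma window
    se <- stats::sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se)
  }
  expect_error(sample_henyey_greenstein(1, 0.5), "\\[0, 1\\)")
  expect_error(sample_henyey_greenstein(0.5, 1), "\\[0, 1\\)")
})

test_that("Fresnel reflectance covers matched, normal and total internal cases", {
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.7), 0)
  expect_equal(fresnel_reflectance(1, 1.4, 1), ((1 - 1.4) / (1 + 1.4))^2,
               tolerance = 1e-12)
  # beyond the critical angle from dense to rare: everything reflects
  crit_cos <- sqrt(1 - (1 / 1.4)^2)
  expect_equal(fresnel_reflectance(1.4, 1, crit_cos * 0.5), 1)
  expect_true(all(fresnel_reflectance(1, 1.5, seq(0, 1, 0.1)) >= 0))
  expect_error(fresnel_reflectance(0.8, 1.2, 0.5), ">= 1")
})

test_that("weight bookkeeping closes to 1e-9 for arbitrary media", {
  cases <- list(
    list(st = slab_stack(mu_a_cm = 20), n = 2e4),
    list(st = slab_stack(mu_a_cm = 1, mu_s_prime_cm = 15, g = 0.9, n = 1.4),
         n = 5e3),
    list(st = thz_skin_stack(), n = 2e4),
    list(st = synth_stack(9, n_layers = 3, mu_a_range = c(200, 2000),
                          mu_s_prime_range = c(0, 1000)), n = 5e3))
  for (cs in cases) {
    g <- axi_grid(cs$st, dr = 1e-3, dz = total_depth(cs$st) / 40,
                  r_max = 0.02)
    mc <- run_mc(cs$st, gaussian_source(0.1, 0.004), g,
                 mc_settings(n_photons = cs$n, seed = 3))
    expect_lt(abs(sum(mc$fractions) - 1), 1e-9)
    expect_true(all(mc$fractions >= 0))
  }
})

test_that("tallies are bit-identical for the same seed, close for another", {
  st <- thz_skin_stack()
  g <- axi_grid(st, dr = 1e-3, dz = c(2e-5, 1e-4, 2e-4), r_max = 0.03)
  src <- gaussian_source(0.1, 0.004)
  a <- run_mc(st, src, g, mc_settings(n_photons = 3e4, seed = 11))
  b <- run_mc(st, src, g, mc_settings(n_photons = 3e4, seed = 11))
  expect_identical(a$absorbed, b$absorbed)
  expect_identical(a$fractions, b$fractions)
  # independent seeds agree on layer fractions within 4 combined sigma
  c2 <- run_mc(st, src, g, mc_settings(n_photons = 3e4, seed = 12))
  se_bin <- function(f, n) sqrt(pmax(f * (1 - f), 1e-12) / n)
  fa <- a$layer_fractions$fraction; fc <- c2$layer_fractions$fraction
  comb <- sqrt(se_bin(fa, 3e4)^2 + se_bin(fc, 3e4)^2)
  expect_true(all(abs(fa - fc) <= 4 * comb))
})

test_that("absorption-only centerline matches Beer-Lambert within 3 sigma", {
  mu_a <- 2000
  st <- slab_stack(mu_a_cm = mu_a / 100, thickness_mm = 3)
  g <- axi_grid(st, dr = 1e-3, dz = 5e-5, r_max = 0.02)
  mc <- run_mc(st, gaussian_source(0.1, 0.004), g,
               mc_settings(n_photons = 2e5, seed = 5))
  p <- centerline_profile(mc)
  # cell-averaged closed form, normalized like the tally
  zl <- head(g$z_edges, -1); zh <- tail(g$z_edges, -1)
  ref <- (exp(-mu_a * zl) - exp(-mu_a * zh)) / (mu_a * (zh - zl))
  ref <- ref / ref[1]
  sel <- ref > 1e-3
  expect_true(all(abs(p$value[sel] - ref[sel]) <=
                    3 * pmax(p$stderr[sel], 1e-12)))
  # slope of the log profile recovers mu_a
  fit <- lm(log(p$value[sel]) ~ g$z[sel])
  expect_equal(unname(coef(fit)[2]), -mu_a, tolerance = 0.05)
})

test_that("normal-incidence specular split matches the Fresnel closed form", {
  st <- slab_stack(mu_a_cm = 50, n = 1.4)
  g <- axi_grid(st, dr = 1e-3, dz = 1e-4, r_max = 0.02)
  mc <- run_mc(st, gaussian_source(0.1, 0.004), g,
               mc_settings(n_photons = 1e4, seed = 2, ambient_n = 1))
  expect_equal(unname(mc$fractions["specular"]),
               ((1 - 1.4) / (1 + 1.4))^2, tolerance = 1e-6)
})

test_that("layer absorption is insensitive to anisotropy at fixed mu_s'", {
  # similarity relation: exact only in the diffusive regime, so use layers
  # many transport mean free paths thick and allow a one-point systematic
  # margin on top of the counting noise for the residual near-source
  # mismatch
  base <- function(g_hg) {
    st <- tissue_stack(dplyr::bind_rows(
      layer("top", 2, 1, 50, g = g_hg),
      layer("bottom", 3, 2, 50, g = g_hg)))
    gr <- axi_grid(st, dr = 1e-3, dz = 2e-4, r_max = 0.02)
    run_mc(st, gaussian_source(0.1, 0.004), gr,
           mc_settings(n_photons = 3e4, seed = 8))$layer_fractions$fraction
  }
  f0 <- base(0); f9 <- base(0.9)
  se <- sqrt(pmax(f0 * (1 - f0), 1e-12) / 3e4) * sqrt(2)
  expect_true(all(abs(f0 - f9) <= 3 * se + 0.01))
})

test_that("invalid Monte Carlo settings are rejected", {
  expect_error(mc_settings(n_photons = 0), ">= 1")
  expect_error(mc_settings(roulette_survival = 1), "\\(0, 1\\)")
  expect_error(mc_settings(roulette_threshold = 0), "\\(0, 1\\)")
  clear <- tissue_stack(layer("clear", 1, 0))
  g <- axi_grid(clear, dr = 1e-3, dz = 1e-4, r_max = 0.01)
  expect_error(run_mc(clear, gaussian_source(0.1, 0.003), g),
               "at least one layer")
})
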