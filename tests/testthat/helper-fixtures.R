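# Shared in-code fixtures. Everything is generated here; no data files.

# the three-layer sub-THz skin stack (absorption coefficients in cm^-1)
thz_skin_stack <- function(mu_a_cm = c(50, 70, 7)) {
  tissue_stack(dplyr::bind_rows(
    layer("epidermis", 0.2, mu_a_cm[1]),
    layer("dermis", 1.0, mu_a_cm[2], perfused = TRUE),
    layer("fat", 1.6, mu_a_cm[3], perfused = TRUE)
  ))
}

# homogeneous absorbing slab for closed-form oracles
slab_stack <- function(mu_a_cm = 20, thickness_mm = 4, mu_s_prime_cm = 0,
                       g = 0, n = 1, perfused = TRUE) {
  tissue_stack(layer("slab", thickness_mm, mu_a_cm, mu_s_prime_cm,
                     g = g, n = n, perfused = perfused))
}

coarse_grid <- function(stack, dz = 2e-5, dr = 1e-3, r_max = 0.03) {
  axi_grid(stack, dr = dr, dz = dz, r_max = r_max)
}

# scenario config coarsened for fast thermal tests
coarse_config <- function(name = "thz_130ghz") {
  cfg <- scenario(name)
  cfg$grid$dr_mm <- 2
  cfg$grid$dz_mm <- unlist(cfg$grid$dz_mm) * 2
  cfg$thermal$dt_s <- 5
  cfg$thermal$t_end_s <- 200
  cfg
}
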