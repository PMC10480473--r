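Package: skintherm
Title: Coupled Tissue-Optics and Bioheat Simulation of Skin Under
    Terahertz and Optical Beams
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates electromagnetic exposure of layered human skin and
    the resulting temperature rise. Three optics backends compute the
    light/millimetre-wave dose in an axisymmetric layered medium: a
    layered Beer-Lambert closed form, a steady-state diffusion
    approximation of the radiative transfer equation solved by sparse
    finite volumes, and an MCML-style Monte Carlo photon transport with
    Henyey-Greenstein scattering, Fresnel interfaces and Russian
    roulette. The absorbed power density drives a transient Pennes
    bioheat solver with blood perfusion feedback, metabolic heat, a
    convective skin boundary and square-wave pulsed sources, yielding
    photothermal dose-response curves for continuous and duty-cycled
    exposure. Scenario fixtures, parametric sweeps (power, beam waist,
    duty cycle) and a synthetic stack generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
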