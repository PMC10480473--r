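# skintherm

Coupled tissue-optics and bioheat simulation of human skin under
terahertz-band and optical beams.

As wireless systems move above 100 GHz and photonic sources proliferate,
skin becomes the first — and often the only — tissue the radiation reaches:
water absorbs strongly in the sub-THz/THz bands, so the power of a 6G-style
beam is deposited within the top few hundred micrometres and heats it.
skintherm is for dosimetry and bio-electromagnetics work that needs to
answer, quantitatively: *where does the beam power go in layered skin, and
how much does the tissue warm up under continuous or pulsed exposure?*

## The model

Two stages share one axisymmetric `(r, z)` grid over a layered stack
(epidermis / dermis / blood-infused fat in the shipped scenarios).

**Optics** — three interchangeable backends compute the absorbed power
density `q_abs(r, z)` of a Gaussian beam (power `P`, 1/e² intensity radius
`w`):

* layered Beer–Lambert: `I(z)/I₀ = exp(−Σ (μₐ+μₛ′) dℓ)` — the 1D
  analytical reference;
* diffusion approximation of the radiative transfer equation:
  `−∇·(D∇Φ) + μₐΦ = 0` with `D = 1/(3(μₐ+μₛ′))` and Dirichlet Gaussian
  incidence, solved by sparse finite volumes — the primary backend;
* MCML-style Monte Carlo photon transport (hop/drop/spin with weights,
  Henyey–Greenstein scattering, Fresnel interfaces, Russian roulette) —
  the validation backend.

**Bioheat** — the transient Pennes equation driven by `q_abs` modulated by
a square-wave pulse schedule `s(t)`:

```
ρ c_p ∂T/∂t = ∇·(k ∇T) + ρ_b c_{p,b} ω_b (T_b − T) + Q_met + q_abs · s(t)
```

with convective cooling `−k ∂T/∂z = h (T − T_amb)` at the surface and
insulated far boundaries; perfusion acts as the body's negative feedback.
Rises are reported against the no-source baseline field. Implicit time
stepping; plateaus come from the stationary solve the linear system
asymptotes to, verified against the transient.

See `vignettes/photothermal-dosimetry.Rmd` for the conventions
(diffusion-coefficient choice, energy normalization, pulsed-orbit
integration) and all default parameter values.

## Worked example

```r
library(skintherm)
cfg <- scenario("thz_130ghz")          # 130 GHz, 100 mW, 2 cm waist
st  <- config_stack(cfg)

# where does the beam power go?
field <- solve_fluence(st, config_source(cfg), config_grid(cfg))
absorbed_fraction_by_layer(field, st)
#>   layer        fraction
#> 1 epidermis 0.824
#> 2 dermis    0.176
#> 3 fat       0.000000725

# how hot does it get?
res <- run_scenario(cfg)
res$plateau
#> [1] 4.377338
tail(tidy(res$temperature), 3)
#>       t T_max_rise
#> 1  2996       4.37
#> 2  2998       4.37
#> 3  3000       4.37

# pulsed exposure: duty cycle halves the plateau, frequency is irrelevant
duty_cycle_sweep(cfg, duties = c(1, 0.5), frequencies = c(1, 100))
#>   duty_cycle frequency plateau_rise
#> 1        1           1         4.38
#> 2        0.5         1         2.21
#> 3        1         100         4.38
#> 4        0.5       100         2.19
```

Reading the numbers: at 130 GHz the 0.2 mm epidermis absorbs 82% of the
beam power (effective attenuation `√3·μₐ` with `μₐ = 50 cm⁻¹`), and a
continuous 100 mW / 2 cm beam warms the skin by about 4.4 K at the plateau
— the asymptote of the feedback between deposition, perfusion, and surface
convection. Temperature magnitudes carry the uncertainty of the thermal
property set (documented defaults; roughly ±30%), while ratios are sharp:
rises scale exactly linearly with power, and a 50% duty cycle halves the
plateau whether the source pulses at 1 Hz or 100 Hz.

Scenarios are YAML files (`inst/scenarios/`): `thz_130ghz`, `thz_1thz`,
`nir_1030nm` (scattering-dominated near-infrared), `bacon` (non-living
bench exposure). `compare_optics(cfg)` returns the three backends'
centerline profiles side by side; `power_sweep()`, `waist_sweep()` and
`duty_cycle_sweep()` drive parametric studies; a thin CLI lives at
`inst/cli/skintherm`.

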