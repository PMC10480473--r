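---
title: "Photothermal dosimetry of layered skin: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photothermal dosimetry of layered skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skintherm)
```

skintherm predicts the temperature rise in layered human skin exposed to a
millimetre-wave, terahertz or near-infrared Gaussian beam. It couples two
stages on one shared axisymmetric `(r, z)` grid: an optics stage that
computes where the beam power is deposited, and a transient Pennes bioheat
stage that turns that deposition into a temperature field. This vignette is
the package's own account of the models, the conventions it commits to, and
the numerical decisions a careful user should know about.

## The tissue model

The medium is a stack of plane-parallel layers (epidermis, dermis,
blood-infused fat in the shipped scenarios), each with optical properties
(absorption coefficient $\mu_a$, reduced scattering coefficient $\mu_s'$,
anisotropy $g$, refractive index $n$) and thermal properties (density
$\rho$, specific heat $c_p$, conductivity $k$). Depth intervals are
half-open, $[z_{\mathrm{top}}, z_{\mathrm{bot}})$, so a point exactly on an
interface belongs to the layer below — this makes depth lookup unambiguous.
Internally everything is SI; the config files accept the units the field
customarily prints (mm, cm$^{-1}$) and convert exactly once on load.

`z = 0` is the air–tissue interface. The air above the skin is not part of
either solver grid: optical incidence and convective cooling are boundary
conditions at `z = 0`. The beam waist $w$ is the $1/e^2$ *intensity radius*,
so the surface irradiance is $I(r) = \frac{2P}{\pi w^2} e^{-2r^2/w^2}$.
(The literature this package follows does not state whether its quoted
"2 cm beam waist" is a radius or a diameter; the radius reading is used
throughout.)

## Optics stage: three backends

**Beer–Lambert** (`beer_lambert_profile()`). The 1D analytical reference:
$I(z)/I_0 = \exp\!\big(-\sum_\ell (\mu_{a,\ell} + \mu_{s,\ell}')\,d_\ell\big)$
over the traversed layers — scattering is counted as attenuation, as the
classical analytical treatment does. Exact, grid-free, and the oracle for
the other two backends in absorption-dominated media.

**Diffusion approximation** (`solve_fluence()`). The steady-state fluence
rate $\Phi$ solves
$$-\nabla\cdot(D\nabla\Phi) + \mu_a \Phi = 0, \qquad
\Phi(r, 0) = \tfrac{2P}{\pi w^2}e^{-2r^2/w^2},$$
with Neumann symmetry at $r=0$ and zero-fluence (or optionally Robin) far
boundaries. The transient $\frac{1}{v}\partial_t\Phi$ term is dropped:
light transport equilibrates in picoseconds while the thermal problem
evolves over seconds, so only the stationary field matters to the coupling.

Two conventions for the diffusion coefficient are selectable:

* `standard_third` (default): $D = \frac{1}{3(\mu_a + \mu_s')}$, the
  textbook convention, giving an effective attenuation
  $\mu_{\mathrm{eff}} = \sqrt{3\mu_a(\mu_a+\mu_s')}$. In the sub-THz
  scenarios ($\mu_s' = 0$) this reproduces the reported layer splits:
  $1 - e^{-\sqrt3 \cdot 50\,\mathrm{cm^{-1}} \cdot 0.02\,\mathrm{cm}}
  \approx 0.82$ of the power in the 0.2 mm epidermis at 130 GHz, and
  $\approx 0.99$ at 1 THz.
* `paper_literal`: $D = \frac{1}{\mu_a + \mu_s'}$, under which a
  non-scattering medium decays as $e^{-\mu_a z}$, i.e. the centerline
  coincides with Beer–Lambert. Useful for literal replication of the
  source formulation; it cannot reproduce the ~80%/99% epidermal splits
  above.

No specular or interface reflections are modelled in this backend (uniform
refractive index assumption), matching the formulation it implements.

**Monte Carlo** (`run_mc()`). MCML-style photon transport: collimated
normal incidence with radius sampled from the Gaussian intensity profile;
hop lengths $-\ln U/(\mu_a+\mu_s)$ with $\mu_s = \mu_s'/(1-g)$; a
$\mu_a/(\mu_a+\mu_s)$ weight share deposited per interaction into the local
grid cell; Henyey–Greenstein direction updates; unpolarized Fresnel
reflection/refraction wherever refractive indices mismatch; Russian
roulette (threshold $10^{-4}$, survival 0.1) on low weights. Photons that
wander beyond the scoring radius keep propagating; their absorbed weight is
booked per layer off-grid so energy accounting stays closed. The default
comparison mode runs with uniform $n$, mirroring the diffusion backend's
no-reflection assumption; the NIR fixture uses tissue $n = 1.4$ under air.

*Roulette bookkeeping.* True Russian roulette conserves weight only in
expectation, not per run. The tally therefore tracks the net roulette
residual (killed weight minus survivor boosts, zero-mean) and reports the
four weight fractions — specular, diffuse reflectance, transmittance,
absorbed — normalized by the accounted weight. The four fractions then sum
to 1 exactly on every run, and the residual (typically $10^{-5}$ relative)
is exposed in `glance()`.

*Uncertainty.* Photons are split into independent batches (16 by default);
per-cell standard errors come from the batch variance and propagate into
the centerline profile.

## Energy normalization: one decision, stated plainly

Under `standard_third`, the Dirichlet surface condition delivers a boundary
influx of $P/\sqrt3$ for a non-scattering medium — the price of pinning the
*fluence* at the surface to the incident *irradiance*. The package keeps
two books consistently:

* Within the optics stage, absorbed/escaped fractions are normalized by the
  computed boundary influx, so "fractions + escaped = 1" holds to solver
  tolerance and the 82%/99% layer splits are well defined.
* At the coupling step (`absorbed_power_density()`), the deposition *shape*
  from the optics stage is rescaled so the tissue receives the full beam
  power $P$ (less any far-boundary escape). This reflects the no-reflection
  assumption — everything the source emits enters the tissue — and makes
  "100 mW exposure" mean 100 mW of heat.

## Bioheat stage

The Pennes equation on the same grid:
$$\rho c_p \frac{\partial T}{\partial t} = \nabla\cdot(k\nabla T)
  + \rho_b c_{p,b}\,\omega_b (T_b - T) + Q_{met} + q_{abs}\, s(t),$$
with convective flux $-k\,\partial_z T = h(T - T_{amb})$ at the surface and
insulated far boundaries. The advective term $\rho c_p\,\mathbf u\cdot\nabla T$
of the general formulation is carried with $\mathbf u = 0$: bulk perfusion
is represented solely by the sink term, the standard Pennes usage (no
velocity field is available to do better). $s(t)$ is the unit square wave
of the pulse schedule — 1 during the ON phase of each period, determined by
the duty cycle and repetition frequency — and identically 1 for continuous
exposure.

Temperature rises are always reported relative to the no-source *baseline*
field (`solve_baseline()`), not to a uniform 37 °C: surface convection
makes the unexposed steady state non-uniform (about 30 °C at the surface
with the defaults below), and the published dose-response curves are rises.
Because the system is linear, the rise field obeys the same operator with
homogeneous boundary data, so the transient solver integrates the rise
directly.

Two implicit schemes are available (backward Euler default,
Crank–Nicolson optional); the near-surface deposition at THz frequencies is
stiff, so explicit stepping is deliberately not offered. Pulsed runs
subdivide steps at switching instants so $s(t)$ is piecewise-constant per
step, and refuse time steps coarser than a tenth of the ON phase.

**Plateaus.** The linearity of the discrete system means the asymptote of
the transient scheme *is* the stationary solve `plateau_rise()`
($K\theta = \mathrm{duty}\cdot q_{abs}V$); the test suite verifies the
transient lands on it to better than 1%. For pulsed exposure,
`pulsed_plateau_rise()` integrates the periodic orbit directly: it starts
from the duty-scaled stationary field (the cycle-averaged asymptote) and
steps fine-resolution cycles until consecutive per-cycle maxima agree,
reporting the converged per-cycle maximum. At 1 Hz this ripple adds about
1% over the cycle mean; at 100 Hz it is negligible — which is why the
plateau depends on the duty cycle but not on the repetition frequency.

## Default parameters

The source literature publishes no thermal property values, so the package
documents and defaults to standard skin values; they are overridable per
layer and per scenario, and the quantitative temperature results inherit
their uncertainty (roughly ±30%):

| parameter | default | units | note |
|---|---|---|---|
| $k$ | 0.5 | W/(m K) | all tissue layers |
| $\rho$ | 1050 | kg/m³ | |
| $c_p$ | 3600 | J/(kg K) | |
| $\rho_b, c_{p,b}$ | 1060, 3600 | kg/m³, J/(kg K) | blood |
| $\omega_b$ | $10^{-3}$ | 1/s | dermis and fat only; epidermis avascular |
| $T_b$ | 310.15 | K | arterial blood |
| $Q_{met}$ | 1000 | W/m³ | all tissue layers |
| $h$ | 10 | W/(m² K) | still-air convection |
| $T_{amb}$ | 296.15 | K | 23 °C |

With this set, the 130 GHz / 100 mW / 2 cm-waist exposure plateaus at
4.4 K — the right scale for the ~6 K literature value but at the low edge
of the parameter-uncertainty band; a quieter boundary layer (smaller $h$)
or weaker perfusion moves it up. The *ratios* the package computes are
insensitive to this set: power linearity is exact (the operator is
linear), and the 50% duty plateau is half the continuous one at any
repetition frequency from 1 to 100 Hz.

The 1030 nm scenario ships literature-style coefficients for pigmented
skin (epidermis $\mu_a$ 2.5 cm⁻¹ / $\mu_s'$ 30 cm⁻¹, dermis 2.0/30, fat
1.5/25, $g = 0.9$, $n = 1.4$), because the source cites but does not print
its table. Tests on this fixture are therefore qualitative only: the Monte
Carlo centerline peaks below the surface near the epidermis–dermis
boundary while the Dirichlet diffusion profile is monotone, and the
centerline intensity is "near zero" by 3 mm. Near zero is operationalized
as < 0.05 (diffusion, Beer–Lambert) and < 0.10 (Monte Carlo, which is
normalized at the first cell below its subsurface peak) at the deepest
grid plane: with any diffusive NIR-credible coefficient set the normalized
fluence at 2.8 mm is bounded below by $e^{-\mu_{\mathrm{eff}} z}$ with
$\mu_{\mathrm{eff}} \sim 10\text{–}15$ cm⁻¹, so thresholds much below a
few percent are not attainable and would test the coefficients, not the
solvers.

## Numerical choices

* **Grids.** Finite-volume cells; axial edges snap to layer interfaces so
  every cell lies in one layer; radial annuli are uniform. The shipped THz
  scenarios use ~120 × 100–150 cells (dr 0.5 mm; dz 10 µm in the epidermis,
  5 µm at 1 THz where $1/\mu_{\mathrm{eff}} \approx 42$ µm). Halving the
  spacing moves the epidermal absorbed fraction by < 0.05%.
* **Diffusion solve.** Sparse SPD 5-point system, direct solve; harmonic
  averaging of $D$ (and of $k$ in the thermal stage) on faces crossing
  interfaces preserves flux continuity. Discrete conservation (influx =
  absorbed + escaped) is checked on every solve and enforced to $10^{-8}$
  relative.
* **Far boundaries.** The "semi-infinite surround" is emulated by a domain
  at least 3 beam waists wide with zero-fluence (optics) / insulated
  (thermal) conditions; waist sweeps grow the domain with the beam.
* **Transients.** Backward Euler with a cached Cholesky factor per distinct
  step size; 3000 s at dt = 2 s covers the slowest thermal time constant
  (~500 s, set by tissue heat capacity against perfusion + convection) and
  the reported plateau is accepted only if the late-time slope is below
  $10^{-4}$ K/s.
* **Monte Carlo.** $10^5$–$10^6$ photons depending on the scenario
  (absorption-only THz media need one interaction per photon and run in
  under a second per $10^6$); fixed seeds make every tally bit-reproducible
  from the config.
* **Degenerate inputs.** Zero-power sources give zero fields and zero
  fractions (profiles cannot be normalized and say so); layers with
  $\mu_a + \mu_s' = 0$ are rejected by the diffusion backend (undefined
  $D$); `h = 0` with no perfused layer is rejected as an unbounded steady
  state; Monte Carlo cells with $\mu_a = 0$ report fluence as `NA` rather
  than dividing by zero.

## What the synthetic generator does and does not emulate

`synth_stack()` draws random layered media (thicknesses, coefficients,
anisotropy from stated ranges, fixed seed) so that property tests — volume
conservation, lookup consistency, conservation identities, closed-form
limits — run on inputs nobody hand-picked. It emulates plane-parallel
layered tissue only: no curvature, no lateral heterogeneity, no vasculature
geometry, no frequency-dependent dielectric response ($\mu_a$ is an input,
as in the source formulation). Passing tests therefore demonstrate solver
correctness on the layered idealization, not fidelity of any particular
coefficient set to a particular person's skin.

## Known limitations

* The diffusion approximation is quantitatively poor in the
  scattering-dominated NIR regime near the source — by construction it has
  no subsurface buildup under a Dirichlet surface condition — and should be
  read as an approximation there; Monte Carlo is the reference.
* Pure Pennes: no thermal damage integrals, no temperature-dependent
  perfusion, no phase change. Multi-ten-kelvin plateaus (the 1 W exposure)
  are extrapolations of the linear model into a regime where real tissue
  would be injured.
* The bacon scenario models only the focal-region exposure with an
  effective 2 cm spot; lens optics are out of scope and its absorption
  coefficient is a user-supplied stand-in.
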