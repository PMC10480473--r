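# Near-infrared (1030 nm, 0.29 PHz) exposure: low absorption, strong forward
# scattering, deep penetration. The published study cites but does not print
# its coefficient table, so these are editable literature-style defaults for
# pigmented skin at 1030 nm; tests on this fixture assert qualitative
# behaviour only (subsurface Monte Carlo fluence peak, near-zero intensity
# by 3 mm).
name: nir_1030nm
stack:
  layers:
  - name: epidermis
    thickness_mm: 0.2
    mu_a_per_cm: 2.5
    mu_s_prime_per_cm: 30.0
    g: 0.9
    refractive_index: 1.4
    rho_kg_m3: 1050.0
    c_p_J_per_kgK: 3600.0
    k_W_per_mK: 0.5
    perfused: false
  - name: dermis
    thickness_mm: 1.0
    mu_a_per_cm: 2.0
    mu_s_prime_per_cm: 30.0
    g: 0.9
    refractive_index: 1.4
    rho_kg_m3: 1050.0
    c_p_J_per_kgK: 3600.0
    k_W_per_mK: 0.5
    perfused: true
  - name: fat
    thickness_mm: 1.6
    mu_a_per_cm: 1.5
    mu_s_prime_per_cm: 25.0
    g: 0.9
    refractive_index: 1.4
    rho_kg_m3: 1050.0
    c_p_J_per_kgK: 3600.0
    k_W_per_mK: 0.5
    perfused: true
  blood:
    rho_b_kg_m3: 1060.0
    c_pb_J_per_kgK: 3600.0
    omega_b_per_s: 0.001
    T_b_K: 310.15
    q_met_W_per_m3: 1000.0
source:
  power_W: 0.1
  waist_mm: 5.0
  profile: gaussian
  duty_cycle: 1.0
  pulse_frequency_Hz: 1.0
grid:
  dr_mm: 0.5
  dz_mm: [0.01, 0.025, 0.05]
  r_max_mm: 30.0
thermal:
  h_W_per_m2K: 10.0
  T_ambient_K: 296.15
  dt_s: 2.0
  t_end_s: 3000.0
optics:
  backend: diffusion
  convention: standard_third
  far_boundary: zero_fluence
  mc_n_photons: 150000
  mc_seed: 1
  mc_ambient_n: 1.0
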