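# Non-living tissue (bacon) under the 130 GHz bench source. Only the
# focal-region exposure is modelled: the collimated 5.5 cm beam focused to a
# ~2 cm spot is represented as an effective 2 cm-waist source; lens optics
# are out of scope. The absorption coefficient is user-supplied (external
# measured values for fatty tissue at 130 GHz); thermal properties are
# fat-like. No perfusion, no metabolism: the sample is not alive.
name: bacon
stack:
  layers:
  - name: bacon
    thickness_mm: 5.0
    mu_a_per_cm: 10.0
    mu_s_prime_per_cm: 0.0
    g: 0.0
    refractive_index: 1.0
    rho_kg_m3: 920.0
    c_p_J_per_kgK: 2500.0
    k_W_per_mK: 0.2
    perfused: false
  blood:
    rho_b_kg_m3: 1060.0
    c_pb_J_per_kgK: 3600.0
    omega_b_per_s: 0.0
    T_b_K: 295.95
    q_met_W_per_m3: 0.0
source:
  power_W: 0.02
  waist_mm: 20.0
  profile: gaussian
  duty_cycle: 1.0
  pulse_frequency_Hz: 1.0
grid:
  dr_mm: 0.5
  dz_mm: 0.05
  r_max_mm: 60.0
thermal:
  h_W_per_m2K: 10.0
  T_ambient_K: 295.95
  dt_s: 2.0
  t_end_s: 1000.0
optics:
  backend: diffusion
  convention: standard_third
  far_boundary: zero_fluence
  mc_n_photons: 200000
  mc_seed: 1
  mc_ambient_n: 1.0
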