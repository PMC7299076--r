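passive:
  K: 3333000.0
  a: 59.0
  b: 8.023
  af: 18472.0
  bf: 16.026
  as: 2564.0
  bs: 11.12
  afs: 216.0
  bfs: 11.436
land:
  k_trpn: 0.1
  n_trpn: 2.0
  ca_t50_ref: 0.805
  ku: 0.04
  n_tm: 2.4
  trpn50: 0.35
  k_uw: 0.182
  k_ws: 0.012
  r_s: 0.25
  r_w: 0.5
  gamma_s: 0.0085
  gamma_w: 0.615
  tot_a: 25.0
  beta_0: 2.3
  beta_1: -2.4
  t_ref: 120000.0
  phi_a: 2.23
  ku_convention: derived_forward_rate
  k_trpn_brackets: whole_bracket
  catrpn_floor: 1.0e-08
active_stress:
  kort1: 0.0
  kort2: 0.0
  sigma0: 0.0
calcium:
  cmdn_bar: 50.0
  k_cmdn: 2.38
  trpn_max: 70.0
driver:
  diastolic: 0.12
  amplitude: 0.88
  time_to_peak: 25.0
  tau_decay: 140.0
  period: 857.1428571
propagation:
  sigma_f: 0.001
  sigma_s: 0.0005
  sigma_n: 0.00025
  chi: 1400.0
  cm: 1.0
  stimulus_duration: 2.0
sac:
  g: 0.0
  e_rev: -10.0
circulation:
  p0: 20.0
  p_ej: 67.5
  compliance: 0.2
  resistance: 750.0
  gamma: 0.001
  p_fill_threshold: 20.0
  inv_cp0: 25.0
  inv_cv0: 0.0
  inv_cp: 2.0
  inv_cv: 0.0
  t_init: 200.0
  smoothing_window: 3
  inertance: 500.0
geometry:
  edv: 159.43
  wall_thickness: 1.2
  l0: 9.0
fibres:
  phi: 60.0
  k_epi: 200000.0
pacing:
  bpm: 70.0
  n_beats: 1000
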