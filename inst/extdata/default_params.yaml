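# Default parameter file for cardioem.
#
# Units: stresses in Pa unless suffixed; pressures in mmHg in the
# circulation block; times in ms; lengths in cm; volumes in ml;
# calcium concentrations in uM; diffusivities in cm^2/ms.
#
# Provenance notes:
#   passive: the exponential constants (a, b, af, bf, bs, afs, bfs) are the
#     classic simple-shear fit of the orthotropic Holzapfel-Ogden myocardium
#     law; `as` (2564 Pa) and the bulk modulus K (3333 kPa) are the
#     framework's baseline values.
#   land: constants of the published human active-contraction (Land) model;
#     they are not re-fitted here. `ku_convention` records that the blocked-
#     site forward rate K_u is derived from the single unbinding rate ku as
#     K_u = ku * trpn50^n_tm / (1 - rs - (1 - rs) * rw).
#   calcium: calmodulin/troponin buffering constants of the human ventricular
#     ionic model family, converted to uM.
#   driver: synthetic calcium transient emulating a healthy human ventricular
#     myocyte at 70 bpm (peak ~1 uM, diastolic ~0.12 uM).
#   propagation: orthotropic diffusivities of the framework; chi and Cm are
#     standard monodomain values (not printed in the framework description).

passive:
  K: 3333000.0        # Pa (3333 kPa baseline bulk modulus)
  a: 59.0             # Pa
  b: 8.023
  af: 18472.0         # Pa
  bf: 16.026
  as: 2564.0          # Pa (baseline)
  bs: 11.12
  afs: 216.0          # Pa
  bfs: 11.436

land:
  k_trpn: 0.1         # 1/ms
  n_trpn: 2.0
  ca_t50_ref: 0.805   # uM
  ku: 0.04            # 1/ms (unbinding rate, backward B rate)
  n_tm: 2.4
  trpn50: 0.35
  k_uw: 0.182         # 1/ms
  k_ws: 0.012         # 1/ms
  r_s: 0.25
  r_w: 0.5
  gamma_s: 0.0085     # 1/ms
  gamma_w: 0.615      # 1/ms
  tot_a: 25.0
  beta_0: 2.3
  beta_1: -2.4        # uM
  t_ref: 120000.0     # Pa (120 kPa baseline)
  phi_a: 2.23         # distortion-decay scaling
  ku_convention: derived_forward_rate
  k_trpn_brackets: whole_bracket   # k_trpn multiplies both bracket terms
  catrpn_floor: 1.0e-08

active_stress:
  kort1: 0.0
  kort2: 0.0          # baseline
  sigma0: 0.0         # Pa, initial pre-stress before initiation

calcium:
  cmdn_bar: 50.0      # uM
  k_cmdn: 2.38        # uM
  trpn_max: 70.0      # uM

driver:
  diastolic: 0.12     # uM
  amplitude: 0.88     # uM (peak ~ 1.0 uM)
  time_to_peak: 25.0  # ms
  tau_decay: 140.0    # ms
  period: 857.1428571428571  # ms (70 bpm)

propagation:
  sigma_f: 0.001      # cm^2/ms
  sigma_s: 0.0005     # cm^2/ms
  sigma_n: 0.00025    # cm^2/ms
  chi: 1400.0         # 1/cm
  cm: 1.0             # uF/cm^2
  stimulus_duration: 2.0  # ms

sac:
  g: 0.0              # maximal conductance; inactive by default
  e_rev: -10.0        # mV

circulation:
  p0: 20.0            # mmHg end-diastolic pressure
  p_ej: 67.5          # mmHg ejection trigger
  compliance: 0.2     # ml/mmHg
  resistance: 750.0   # mmHg ms/ml
  gamma: 0.001        # mmHg/ml filling decay constant (near-isobaric filling)
  p_fill_threshold: 20.0  # mmHg (defaults to p0)
  inv_cp0: 25.0       # mmHg/ml  (1/Cp0, initiation volume penalty, sigma0 in mmHg per ml)
  inv_cv0: 0.0        # mmHg ms/ml (1/Cv0, initiation rate stabilisation)
  inv_cp: 2.0         # mmHg/ml  (1/Cp, isovolumetric volume penalty)
  inv_cv: 0.0         # mmHg ms/ml (1/Cv, isovolumetric rate stabilisation)
  t_init: 200.0       # ms, initiation ramp duration
  smoothing_window: 3 # steps, median smoothing of V-dot for flow reversal
  inertance: 500.0    # mmHg ms^2/ml, lumped aortic blood inertance

geometry:
  edv: 159.43         # ml, end-diastolic (reference) cavity volume
  wall_thickness: 1.2 # cm, reference wall thickness
  l0: 9.0             # cm, reference apico-basal cavity length (LFS bookkeeping)

fibres:
  phi: 60.0           # deg, maximal fibre angle (baseline)
  k_epi: 200000.0     # Ba/cm, epicardial spring stiffness (inert in the lumped model)

pacing:
  bpm: 70.0
  n_beats: 1000
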