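---
title: "Methods: a desk-scale coupled ventricular electromechanics model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale coupled ventricular electromechanics model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioem)
```

# What this package models

`cardioem` implements, at desk scale, the building blocks of a strongly
coupled human ventricular electromechanical simulation framework:

* **Excitation–contraction**: the six-state Land active-contraction ODE
  system (`S`, `W`, `CaTRPN`, `B`, `zeta_s`, `zeta_w`), driven by
  intracellular calcium and by the fibre stretch and stretch rate, and
  coupled back to calcium through the troponin buffering term.
* **Passive mechanics**: the quasi-incompressible orthotropic
  Holzapfel–Ogden strain energy and its closed-form second
  Piola–Kirchhoff stress.
* **Active stress**: an orthotropic active stress tensor with weights
  `1 : kort1 : kort2` along the fibre/sheet/normal triad, plus a fibre
  pre-stress `sigma0` calibrated during an initiation phase.
* **Electrical propagation**: the monodomain reaction–diffusion equation on
  1D cables and small 3D boxes, with a deformation-dependent conductivity
  pull-back and a stretch-activated current (off by default).
* **Circulation**: a five-phase cardiac-cycle state machine — initiation,
  isovolumetric contraction, two-element Windkessel ejection, isovolumetric
  relaxation, and decay filling — plus a divergence-theorem cavity-volume
  integral for triangulated endocardial surfaces.
* **Biomarkers and sensitivity**: ejection fraction (EF), end-systolic
  pressure (ESP), longitudinal fractional shortening (LFS) and wall
  thickening (WT); one-at-a-time (OAT) and Latin-hypercube (LHS) designs
  over ten mechanical parameters; and the correlation → partial
  correlation → partial rank correlation (PRCC) chain with significance
  testing.

The organ-scale finite-element discretisation that such frameworks run on
HPC systems is out of scope here. Its role is taken by a *lumped,
thick-walled, incompressible spherical ventricle* whose wall stress comes
from the same constitutive laws, so that full pressure–volume loops and all
four biomarkers can be produced on a laptop.

# The contraction model

The state vector `q = (S, W, CaTRPN, B, zeta_s, zeta_w)` evolves as

* `dS/dt = k_ws W − k_su S − gamma_su(zeta_s) S`
* `dW/dt = k_uw U − k_wu W − k_ws W − gamma_w |zeta_w| W`, with
  `U = 1 − B − S − W`
* `dCaTRPN/dt = k_trpn [ (Ca / CaT50)^n_trpn (1 − CaTRPN) − CaTRPN ]`
* `dB/dt = K_u CaTRPN^(−n_tm/2) U − k_u CaTRPN^(n_tm/2) B`
* `dzeta_{s,w}/dt = A_{s,w} dlam_f/dt − c_{s,w} zeta_{s,w}`

with the length-dependent calcium sensitivity
`CaT50 = CaT50_ref + beta_1 (min(lam_f, 1.2) − 1)` and active tension
`Tact = h(lam_f) (T_ref / r_s) [ (zeta_s + 1) S + zeta_w W ]`, where
`h` is the piecewise-linear length-dependence factor (zero below
`(1.87 b0 − 1)/(2 b0)`, saturating at `1 + 0.2 b0` above `lam_f = 1.2`).

Decisions taken where the printed sources leave room:

* The stretch is `lam_f = sqrt(f0 · C f0)`; only with the square root does
  the stretch equal 1 in the reference configuration and does the active
  stress pull-back close algebraically.
* `gamma_su` is implemented exactly as printed, including its zero-rate gap
  for `zeta_s` in `(−1, 0)`.
* The blocked-site kinetics use two rates: the backward rate `k_u` is the
  source model's single unbinding constant and the forward rate is derived
  as `K_u = k_u trpn50^n_tm / (1 − r_s − (1 − r_s) r_w)`; the parameter file
  records this convention (`ku_convention`).
* `k_trpn` multiplies the whole troponin bracket (recorded as
  `k_trpn_brackets: whole_bracket`).
* `CaTRPN` is floored at `catrpn_floor = 1e-8` inside the negative power so
  the blocking rate cannot diverge at vanishing occupancy.
* Numeric values of the contraction constants are not re-fitted here; they
  are the published human parameter set of the source contraction model and
  live in `inst/extdata/default_params.yaml` with provenance comments, not
  in code.

A useful consequence of the model's structure is that the clamped-calcium,
clamped-stretch steady state is *algebraic*: the distortions vanish,
`CaTRPN` solves a scalar balance in closed form, and `(S, W, B)` solve a
3×3 linear system (`land_steady_state()`). The test suite integrates the
ODEs to `t -> inf` and checks agreement to `1e-8`, which exercises both the
right-hand side and the integrator against an independent oracle.

# Passive and active stress

The strain energy is split volumetric/isochoric, with isochoric invariants
`Ibar = J^(−2/3) I`. The positive-part switch `<x>+` disables the fibre and
sheet exponential terms under compression; as printed it does *not* guard
the fibre-sheet shear term. The closed-form stress uses barred invariants
inside all isochoric factors, consistent with the energy; its correctness is
established against a central finite-difference derivative of the energy on
random deformation states (tolerance `1e-5`, sampled away from the
`I4 = 1` kinks where the energy is not differentiable).

The active stress is assembled in the material frame,

`Sact = (Tact + sigma0)/lam_f^2 f0⊗f0 + kort1 Tact/lam_s^2 s0⊗s0 + kort2 Tact/lam_n^2 n0⊗n0`,

and is verified in the tests to equal the explicit pull-back
`J F^{-1} sigma_act F^{-T}` of the spatial form to `1e-10`. The pre-stress
`sigma0` enters only the fibre term and is treated with the same units and
push-forward convention as `Tact` (one of the open conventions; treating it
otherwise would break the initiation-phase calibration below).

# The circulation state machine

* **Initiation**: the endocardial pressure ramps linearly from 0 to the
  end-diastolic pressure `P0` over `t_init` (default 200 ms). The fibre
  pre-stress is adjusted so the cavity holds its end-diastolic volume. The
  incremental penalty rules (`prestress_update()`,
  `isovolumetric_pressure_update()`) are exposed and tested as per-step
  increment rules; inside the lumped driver the holds are applied in their
  exact limit (the pressure, or pre-stress, that keeps the volume fixed is
  solved directly), which is the limit of an infinitely stiff penalty and
  keeps the isovolumetric drift at round-off instead of a fraction of a
  percent.
* **Isovolumetric contraction** ends when `P_endo` exceeds the ejection
  trigger `P_ej` (the arterial pressure at valve opening).
* **Ejection** couples the wall to the two-element Windkessel
  `C dPart/dt + Part/R = −dV/dt`, integrated with an unconditionally stable
  exact-exponential update. The lumped driver retains a lumped aortic
  inertance (`inertance`, default 500 mmHg·ms²/ml, a literature-typical
  value): the balance law being approximated is dynamic, and it is the
  inertial term that lets the aortic flow decelerate through zero so the
  valve can close by the flow-reversal rule. Flow reversal is detected on a
  3-step median of `dV/dt` to avoid chatter.
* **Isovolumetric relaxation** holds the end-systolic volume while the
  pressure falls with the decaying active tension; it ends when the
  pressure drops below `p_fill_threshold`. The threshold is not prescribed
  by the framework; the default is `P0`, and the driver applies event
  location at the crossing (the filling decay starts exactly at the
  threshold) so that the loop can close.
* **Filling** follows `dP_endo = −gamma dV`. The decay constant is a
  modelling choice; the default `gamma = 0.001` mmHg/ml makes filling
  nearly isobaric at `P0`, which is what allows the volume to return to
  within 1% of the end-diastolic volume given the ventricle's diastolic
  compliance. Filling completes when the volume recovers 99% of EDV.

The cavity-volume operator integrates `(x·a)(a·n)` over a closed
triangulated surface; the integrand is linear per triangle, so each face
contributes exactly `A_T (centroid·a)(a·n_T)`. With the axis in the basal
plane the flat lid contributes nothing; for any closed surface the result
is the enclosed volume for *any* unit axis, which the tests exploit
(icosphere volume to 0.5%, exact `k^3` scaling, truncated-ellipsoid cap
volume against its closed form).

# The lumped ventricle

The ventricle is a thick-walled incompressible sphere with the
end-diastolic cavity volume 159.43 ml and wall thickness 1.2 cm as its
stress-free reference. Fibres are circumferential, sheets transmural.
Incompressible-wall kinematics give the stretch at any wall point from the
cavity volume alone, and the cavity pressure is the thick-wall Laplace
integral `P = ∫ 2(sigma_t − sigma_r)/r dr`, evaluated by midwall quadrature
(default) or 3-point Simpson; the tangential stress is the mean of the
fibre- and normal-direction Cauchy components. Because the sphere's state
is diagonal in the wall frame, the wall stress has a closed-form
specialisation which the tests verify against the full tensor route to
round-off; the driver uses the fast path.

Deliberate consequences of the spherical reduction, all checked or
documented rather than hidden:

* the fibre angle `phi` and the epicardial spring `k_epi` have no
  geometric effect; they are accepted as inert pass-throughs and recorded
  as such when swept (`attr(*, "inert_parameters")`);
* LFS and WT are deterministic functions of the cavity volume, so their
  parameter sensitivities mirror EF's — unlike in the 3D model, where they
  carry independent information;
* `kort2` adds tension in the second tangential direction and therefore
  *raises* EF here, whereas the 3D model reports a negative EF
  correlation; sign checks against the source study are restricted to the
  relationships the sphere can represent (EF/ESP against `T_ref`, `C`,
  `R`, `P_ej`).

A run whose ejection never terminates within the simulated window (the
flow never reverses; it can happen at the stiff-artery corner of the
parameter ranges, e.g. `C = 0.1` with `R = 750`) has no end-systole. Such
runs are flagged `completed = FALSE` with `NA` biomarkers and are excluded
pairwise — never imputed — by the sensitivity layer, which refuses to
report if more than 20% of runs failed.

# The synthetic calcium driver

The cell-level driver replaces a full human ventricular ionic model (an
adapter seam exists: anything that supplies calcium and a net flux can be
plugged in). The synthetic transient is a double-exponential rise–decay,
pinned to zero at both beat ends so it is exactly periodic and continuous,
and normalised so the peak equals diastolic + amplitude. Defaults — 0.12
µM diastolic, 1.0 µM peak, 25 ms time-to-peak, 140 ms decay constant at a
857.14 ms period (70 bpm) — were chosen once as representative of healthy
human ventricular myocyte measurements. In the coupled cell the driver
supplies the *flux* that would reproduce that transient in the absence of
troponin feedback (plus a weak 0.1/ms relaxation toward it); the
`−TRPN_max dCaTRPN/dt` term then genuinely perturbs free calcium, giving a
bidirectional coupling whose buffering factor uses calmodulin constants of
the human ventricular ionic model family.

What the driver does not emulate: rate adaptation and restitution,
alternans, ionic-current pharmacology, SR load dynamics, and
transmural cell-type heterogeneity. Tests that pass with this driver
demonstrate the *coupling machinery*, not ionic-model fidelity.

Pacing at fixed stretch (the initiation protocol: stretch 1, stretch rate
0; defaults 70 bpm for 1000 beats) reaches a beat-to-beat state change
below `1e-6` within a few tens of beats with this driver, so tests and the
acceptance script pace for 40–60 beats; the 1000-beat default is kept as
the protocol value, not a test requirement.

# Electrical propagation

The monodomain operator is split per step into an explicit reaction update
and a backward-Euler diffusion solve with a pre-factorised sparse SPD
system; zero-flux boundaries conserve the total potential exactly (checked
to `1e-10`). The deformation-dependent conductivity is the pull-back
`J [sigma_f/lam_f^2 f0⊗f0 + ...]`; the equivalence identities
`sigma* = J sigma / lam^2` and the `lam^2` reduction under isochoric fibre
extension are verified to `1e-10`.

A two-variable cubic (FitzHugh–Nagumo-type) membrane surrogate is bundled
so wave propagation can be exercised without an ionic adapter. Its
constants (`a = 0.13`, `k = 3/ms`, `eps = 0.002`, `b = 2.5`) were chosen so
a 2 ms edge stimulus elicits a sustained travelling pulse on a 3 cm cable at
the shipped diffusivities; the classic `sqrt(sigma)` conduction-velocity
scaling holds to better than 1% (tested at 5%). Propagation tests run on a
300-node cable (dx = 0.01 cm, dt = 0.02 ms) and an 11×11×3 box — sizes
chosen so the whole suite stays interactive.

# Sensitivity analysis

The OAT design evaluates each parameter at `n_val` uniform grid points
`x = A + (j−1)(B−A)/(n_val−1)` with the others at baseline (10 parameters ×
10 levels = 100 rows); `oat_monotonicity()` counts sign changes along each
sweep, the design's screening purpose. The LHS design stratifies each
parameter range into `n_sam` equal-probability bins with one sample per
bin (uniform distributions; seed mandatory and logged).

The correlation coefficient is implemented directly from its printed
product-moment formula (tested against a from-scratch double-loop
evaluation and `stats::cor` to `1e-12`); the PCC regresses both the column
of interest and the response on the remaining columns (QR decomposition;
rank deficiency is reported with the offending columns) and correlates the
residuals; the PRCC applies the PCC to average ranks. The two-sided
p-value uses `t = r sqrt((N − 2 − k)/(1 − r^2))` with `k` adjusted-for
parameters. Ties get average ranks — for continuous biomarkers they are
measure-zero, so the choice is inert. Null calibration (false-positive
rate at `p <= 0.05` over 100 repeats) and near-perfect recovery of
monotone nonlinear dependencies (`PRCC > 0.99` for a cubic at n = 100) are
part of the acceptance tests.

# Baseline parameters and ranges

The shipped table (`sensitivity_param_table()`) carries the ten swept
parameters with their ranges and baselines; `healthy_ranges()` carries the
clinical biomarker bands (EF 48–69%, ESP 100–174 mmHg, LFS 13–21%, WT
18–100%), with the healthy/diseased EF split at 40% and the
device-guideline threshold at 35%. The baseline `R = 750` sits at the top
of its own range (75–750); it is shipped as printed and flagged with a
warning rather than rejected. Internally stresses are SI pascals;
circulation quantities are exposed in clinical mmHg/ml/ms with conversions
centralised in one file (mmHg, Ba, kPa).

# Numerical settings

| quantity | default | notes |
|---|---|---|
| cell ODE tolerances | rtol 1e-8 / atol 1e-10 | lsoda, pacing |
| contraction integration in the cycle | RK4, dt = cycle dt | distortions backward-Euler against the realised stretch increment during ejection (the stiff feedback loop) |
| cycle time step | 0.5–1 ms | biomarkers agree to 3 significant digits between 1 and 0.5 ms |
| wall quadrature | midwall (1 pt) | 3-pt Simpson available for convergence checks |
| ejection inertance | 500 mmHg·ms²/ml | see circulation section |
| filling decay `gamma` | 0.001 mmHg/ml | near-isobaric filling |
| diffusion solve | backward Euler, sparse Cholesky | factorised once per run |
| volume root solves | `uniroot`, tol 1e-7·EDV | bracket grown from the previous step's volume |

# Known limitations

The sphere cannot represent apico-basal motion, fibre-angle effects, the
epicardial boundary condition, regional strain, or independent LFS/WT
information; quantitative biomarker distributions of the 3D
finite-element study are expressly out of reach at desk scale. The
single-beat protocol measures biomarkers on one triggered heartbeat after
cell-level initiation; the geometry itself is not cycled to a periodic
steady state. WT pairing at a fixed reference height biases WT, as in the
source framework. The synthetic calcium driver and the cubic test
reaction are surrogates with the scope described above.
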