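#' Lumped thick-walled spherical ventricle
#'
#' Desk-scale stand-in for the truncated-ellipsoid finite-element
#' ventricle: a thick-walled incompressible sphere whose wall stress comes
#' from the orthotropic passive law plus the active stress tensor, coupled
#' to the circulation state machine. Fibres are circumferential and sheets
#' transmural, so the fibre-angle and epicardial-spring parameters are
#' geometrically inert here (they are accepted and logged as such when
#' swept).
#'
#' @param edv reference (end-diastolic) cavity volume (ml).
#' @param wall_thickness reference wall thickness (cm).
#' @param l0 reference apico-basal cavity length (cm), bookkeeping for the
#'   longitudinal-shortening biomarker.
#' @return list of class `lumped_geometry` with reference radii (cm) and
#'   the conserved wall volume (ml).
#' @export
lumped_geometry <- function(edv = default_params()$geometry$edv,
                            wall_thickness = default_params()$geometry$wall_thickness,
                            l0 = default_params()$geometry$l0) {
  if (edv <= 0 || wall_thickness <= 0 || l0 <= 0) {
    abort("edv, wall_thickness and l0 must be positive.")
  }
  r_endo0 <- (3 * edv / (4 * pi))^(1 / 3)
  r_epi0 <- r_endo0 + wall_thickness
  structure(
    list(
      r_endo0 = r_endo0, r_epi0 = r_epi0, l0 = l0, edv = edv,
      v_wall = 4 * pi / 3 * (r_epi0^3 - r_endo0^3)
    ),
    class = "lumped_geometry"
  )
}

# incompressible-wall kinematics: deformed radius of the shell material
# point whose reference radius is r0, given the deformed endocardial radius
deformed_radius <- function(r0, r_endo, geom) {
  (r0^3 + r_endo^3 - geom$r_endo0^3)^(1 / 3)
}

# wall quadrature points (reference radii) and weights for the Laplace
# integral; n_quad = 1 is midwall, n_quad = 3 is Simpson
wall_quadrature <- function(geom, n_quad) {
  if (n_quad == 1L) {
    list(r0 = (geom$r_endo0 + geom$r_epi0) / 2, w = 1)
  } else if (n_quad == 3L) {
    list(r0 = c(geom$r_endo0, (geom$r_endo0 + geom$r_epi0) / 2, geom$r_epi0),
         w = c(1, 4, 1) / 6)
  } else {
    abort("n_quad must be 1 or 3.")
  }
}

#' Equilibrium cavity pressure of the lumped ventricle
#'
#' Thick-walled-sphere force balance: from the cavity volume the
#' incompressible-wall kinematics give the circumferential stretch and the
#' (volume-preserving) deformation gradient at each wall quadrature point;
#' the total circumferential and radial Cauchy stresses are evaluated from
#' the passive and active laws and integrated across the wall,
#' `P = integral 2 (sigma_t - sigma_r)/r dr`, by midwall (default) or
#' three-point quadrature. The tangential stress is the mean of the fibre
#' and normal direction components.
#'
#' @param geom a [lumped_geometry()].
#' @param cavity_volume cavity volume (ml, > 0).
#' @param q Land state vector driving the active tension.
#' @param land a [land_params()].
#' @param passive an [ho_params()].
#' @param active an [active_stress_params()] (`sigma0` in Pa).
#' @param n_quad 1 (midwall) or 3 (Simpson) quadrature points.
#' @param tensor evaluate the wall stress through the full tensor machinery
#'   (`TRUE`) or the equivalent closed-form diagonal specialisation
#'   (`FALSE`, default; the two routes agree to round-off and are
#'   cross-checked in the test suite).
#' @return cavity pressure (mmHg).
#' @export
lumped_equilibrium_pressure <- function(geom, cavity_volume, q = land_state(),
                                        land = land_params(),
                                        passive = ho_params(),
                                        active = active_stress_params(),
                                        n_quad = 1L, tensor = FALSE) {
  if (cavity_volume <= 0) abort("cavity collapse: cavity_volume must be positive.")
  r_i <- (3 * cavity_volume / (4 * pi))^(1 / 3)
  quad <- wall_quadrature(geom, n_quad)
  h0 <- geom$r_epi0 - geom$r_endo0
  acc <- 0
  for (k in seq_along(quad$r0)) {
    r0 <- quad$r0[k]
    r <- deformed_radius(r0, r_i, geom)
    lam <- r / r0
    dd <- if (tensor) {
      sphere_stress_tensor(lam, q, land, passive, active)
    } else {
      sphere_stress_fast(lam, q, land, passive, active)
    }
    # dr at the deformed quadrature point: dr = (r0/r)^2 dr0
    acc <- acc + quad$w[k] * 2 * (dd$sigma_t - dd$sigma_r) / r * (r0 / r)^2 * h0
  }
  pa_to_mmhg(acc)
}

# general-tensor route: build F, frame and the full constitutive tensors
sphere_stress_tensor <- function(lam, q, land, passive, active) {
  F <- diag(c(1 / lam^2, lam, lam))  # (radial, circ, circ)
  frame <- fibre_frame(c(0, 1, 0), c(1, 0, 0))  # fibre circumferential, sheet radial
  def <- deformation_state(F)
  inv <- compute_invariants(def$C, frame)
  Tact <- active_tension(q, inv$lam_f, land)
  S <- passive_pk2(def, frame, passive) +
    active_pk2(Tact, def, frame, inv, active)
  sig <- push_forward_stress(S, def)
  list(sigma_t = (sig[2, 2] + sig[3, 3]) / 2, sigma_r = sig[1, 1])
}

# closed-form specialisation for the incompressible sphere: C is diagonal
# diag(lam^-4, lam^2, lam^2) in the (radial, circ, circ) basis, J = 1, so
# the volumetric and fibre-sheet shear terms vanish and the stress is
# diagonal; Cauchy components are F_ii^2 S_ii
sphere_stress_fast <- function(lam, q, land, passive, active) {
  lr2 <- lam^-4   # radial stretch squared
  lc2 <- lam^2    # circumferential stretch squared
  I1 <- lr2 + 2 * lc2
  ciso <- passive$a * exp(passive$b * (I1 - 3))
  # deviatoric isotropic term: S_ii = ciso (1 - I1/(3 C_ii)) ... times Cinv structure
  S_r <- ciso * (1 - I1 / (3 * lr2))
  S_c <- ciso * (1 - I1 / (3 * lc2))
  e4f <- max(lc2 - 1, 0)            # fibre = circumferential (one tangential axis)
  S_f <- 2 * passive$af * e4f * exp(passive$bf * e4f^2)
  e4s <- max(lr2 - 1, 0)            # sheet = radial
  S_s <- 2 * passive$as * e4s * exp(passive$bs * e4s^2)
  # deviatoric projection of the anisotropic terms
  S_r <- S_r + S_s * (1 - lr2 / (3 * lr2)) - S_f * lc2 / (3 * lr2)
  S_c1 <- S_c + S_f * (1 - lc2 / (3 * lc2)) - S_s * lr2 / (3 * lc2)
  S_c2 <- S_c - S_f * lc2 / (3 * lc2) - S_s * lr2 / (3 * lc2)
  Tact <- active_tension(q, lam, land)
  S_c1 <- S_c1 + (Tact + active$sigma0) / lc2          # fibre direction
  S_r <- S_r + active$kort1 * Tact / lr2               # sheet (radial)
  S_c2 <- S_c2 + active$kort2 * Tact / lc2             # normal (other tangential)
  sigma_r <- lr2 * S_r
  sigma_t <- (lc2 * S_c1 + lc2 * S_c2) / 2
  list(sigma_t = sigma_t, sigma_r = sigma_r)
}

# cavity volume solving P_model(V) = p_target near V_guess (quasi-static)
solve_cavity_volume <- function(geom, p_target, V_guess, q, land, passive,
                                active, n_quad = 1L) {
  f <- function(V) {
    lumped_equilibrium_pressure(geom, V, q, land, passive, active, n_quad) - p_target
  }
  lo <- V_guess * 0.98; hi <- V_guess * 1.02
  flo <- f(lo); fhi <- f(hi)
  tries <- 0L
  while (flo * fhi > 0 && tries < 40L) {
    lo <- max(lo * 0.93, 0.05 * geom$edv)
    hi <- min(hi * 1.07, 2.5 * geom$edv)
    flo <- f(lo); fhi <- f(hi)
    tries <- tries + 1L
    if (lo <= 0.05 * geom$edv + 1e-9 && hi >= 2.5 * geom$edv - 1e-9) break
  }
  if (flo * fhi > 0) {
    abort("cavity equilibrium not bracketed; the wall model cannot balance this pressure.")
  }
  uniroot(f, c(lo, hi), tol = 1e-7 * geom$edv)$root
}

#' Run a full cardiac cycle of the lumped ventricle
#'
#' Executes the five-phase state machine on the quasi-static thick-walled
#' sphere: an initiation ramp to end-diastolic pressure that calibrates the
#' fibre pre-stress (the exact limit of the volume-penalty rule, so the
#' cavity holds its end-diastolic volume to round-off), isovolumetric
#' contraction, exact-exponential Windkessel ejection, isovolumetric
#' relaxation, and pressure-decay filling. The Land model is driven by the
#' synthetic calcium transient, with the fibre stretch taken as the lumped
#' midwall circumferential stretch and its rate as a backward difference.
#'
#' @param geom a [lumped_geometry()].
#' @param cell a [cell_system()]; its driver supplies calcium, its Land
#'   block the contraction constants.
#' @param circ a [circulation_params()].
#' @param passive an [ho_params()].
#' @param kort1,kort2 orthotropic activation weights.
#' @param q0 initial Land state (default: algebraic rest state at the
#'   driver's diastolic calcium).
#' @param dt time step (ms).
#' @param duration total simulated time (ms); default: initiation ramp plus
#'   one beat period.
#' @param n_quad wall quadrature points (1 or 3).
#' @param strict error (rather than flag) when a phase never triggers.
#' @return object of class `cardiac_cycle`: list with `trace` (tibble of
#'   `t`, `phase`, `p_endo`, `p_art`, `v_endo`, `sigma_0`, `lambda`,
#'   `wall_thickness`, `cavity_length`, `t_act`, `ca_i`), `sigma_0` (Pa),
#'   `completed`, `phases_reached`, `geom`, and inputs for reproducibility.
#' @export
run_cardiac_cycle <- function(geom = lumped_geometry(), cell = cell_system(),
                              circ = circulation_params(),
                              passive = ho_params(), kort1 = 0, kort2 = 0,
                              q0 = NULL, dt = 0.5, duration = NULL,
                              n_quad = 1L, strict = FALSE) {
  driver <- cell$driver
  land <- cell$land
  if (is.null(q0)) q0 <- land_steady_state(driver$diastolic, 1, land)
  if (is.null(duration)) duration <- circ$t_init + driver$period + 400
  n_steps <- ceiling(duration / dt)
  V0 <- geom$edv
  r_m0 <- (geom$r_endo0 + geom$r_epi0) / 2
  h0 <- geom$r_epi0 - geom$r_endo0

  # a single triggered beat: one calcium transient, then diastolic calcium
  # (the framework evaluates its biomarkers on a single stimulated heartbeat)
  ca_fn <- function(t) {
    if (t <= circ$t_init || t > circ$t_init + driver$period) {
      driver$diastolic
    } else {
      synthetic_transient(t - circ$t_init, driver)
    }
  }
  lam_of_V <- function(V) {
    r_i <- (3 * V / (4 * pi))^(1 / 3)
    deformed_radius(r_m0, r_i, geom) / r_m0
  }

  # pre-stress sensitivity: cavity pressure per unit sigma0 (Pa) at V0
  act0 <- active_stress_params(kort1, kort2, sigma0 = 0)
  act1 <- active_stress_params(kort1, kort2, sigma0 = 1000)
  dP_dsig <- (lumped_equilibrium_pressure(geom, V0, q0, land, passive, act1, n_quad) -
                lumped_equilibrium_pressure(geom, V0, q0, land, passive, act0, n_quad)) / 1000

  q <- unclass(q0)
  V <- V0
  lam_prev <- 1
  sigma0 <- 0
  state <- circulation_state(phase = "initiation", p_endo = 0, p_art = circ$p_ej,
                             v_endo = V0, sigma_0 = 0)
  flow_hist <- numeric()
  Q_out <- 0   # aortic flow (ml/ms), state of the inertial valve dynamics
  rec <- list(
    t = numeric(n_steps), phase = character(n_steps), p_endo = numeric(n_steps),
    p_art = numeric(n_steps), v_endo = numeric(n_steps),
    sigma_0 = numeric(n_steps), lambda = numeric(n_steps),
    wall_thickness = numeric(n_steps), cavity_length = numeric(n_steps),
    t_act = numeric(n_steps), ca_i = numeric(n_steps)
  )
  n_rec <- 0L
  phases_reached <- "initiation"
  esv_time <- NA_real_
  done <- FALSE

  rk4_land <- function(q, t, dt, lam, dlam) {
    f <- function(qq, tt) land_rhs(qq, ca_fn(tt), lam, dlam, land)
    k1 <- f(q, t)
    k2 <- f(q + dt / 2 * k1, t + dt / 2)
    k3 <- f(q + dt / 2 * k2, t + dt / 2)
    k4 <- f(q + dt * k3, t + dt)
    q + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  # backward-Euler distortion update, implicit in the stretch increment: the
  # distortion-tension feedback is stiff against the Windkessel coupling, so
  # zeta is resolved inside the ejection volume solve
  zeta_implicit <- function(zeta0, A, c_rate, dlam_total) {
    (zeta0 + A * dlam_total) / (1 + c_rate * dt)
  }

  for (s in seq_len(n_steps)) {
    t <- s * dt
    lam <- lam_of_V(V)
    dlam <- (lam - lam_prev) / dt
    q_start <- q
    lam_start <- lam
    q <- rk4_land(q, t - dt, dt, lam, dlam)
    lam_prev <- lam
    active <- active_stress_params(kort1, kort2, sigma0 = sigma0)

    if (state$phase == "initiation") {
      p_target <- circ$p0 * min(t / circ$t_init, 1)
      # exact limit of the pre-stress penalty: hold V = EDV and solve the
      # (linear) pre-stress that balances the ramped pressure
      p_base <- lumped_equilibrium_pressure(geom, V0, q, land, passive,
                                            active_stress_params(kort1, kort2, 0),
                                            n_quad)
      sigma0 <- (p_target - p_base) / dP_dsig
      V <- V0
      state$p_endo <- p_target
      state$sigma_0 <- sigma0
      if (t >= circ$t_init) {
        state$phase <- "ivc"   # sigma0 frozen from here on
        phases_reached <- c(phases_reached, "ivc")
      }
    } else if (state$phase == "ivc") {
      V <- V0
      state$p_endo <- lumped_equilibrium_pressure(geom, V, q, land, passive,
                                                  active, n_quad)
      state <- advance_phase(state, circ)
      if (state$phase == "ejection") phases_reached <- c(phases_reached, "ejection")
    } else if (state$phase == "ejection") {
      # ejection with the lumped inertial term of the dynamic balance law:
      # the aortic flow Q obeys L dQ/dt = P_myo(V) - P_art (symplectic
      # Euler: flow first, then volume), the arterial pressure follows the
      # exact-exponential Windkessel update driven by that flow, and the
      # valve closes when the smoothed flow reverses.  Inertia is what lets
      # the flow decelerate through zero when relaxation sets in, as in the
      # dynamic formulation this model reduces.
      zs0 <- q_start[["zeta_s"]]; zw0 <- q_start[["zeta_w"]]
      p_myo <- lumped_equilibrium_pressure(geom, V, q, land, passive,
                                           active, n_quad)
      Q_out <- Q_out + dt / circ$inertance * (p_myo - state$p_art)
      V_new <- max(V - dt * Q_out, 0.1 * geom$edv)
      # distortions re-evaluated against the realised stretch increment
      dlam_total <- lam_of_V(V_new) - lam_start
      q[["zeta_s"]] <- zeta_implicit(zs0, land$A_s, land$c_s, dlam_total)
      q[["zeta_w"]] <- zeta_implicit(zw0, land$A_w, land$c_w, dlam_total)
      state <- windkessel_ejection_step(state, (V_new - V) / dt, dt, circ)
      state$p_endo <- p_myo
      flow_hist <- c(flow_hist, (V_new - V) / dt)
      V <- V_new
      state$v_endo <- V
      state <- advance_phase(state, circ, flow_history = flow_hist)
      if (state$phase == "ivr") {
        phases_reached <- c(phases_reached, "ivr")
        esv_time <- t
        flow_hist <- numeric()
      }
    } else if (state$phase == "ivr") {
      state$p_endo <- lumped_equilibrium_pressure(geom, V, q, land, passive,
                                                  active, n_quad)
      state <- advance_phase(state, circ)
      if (state$phase == "filling") {
        phases_reached <- c(phases_reached, "filling")
        # event location: the threshold is crossed within this step, so the
        # filling decay starts exactly at the threshold pressure
        state$p_endo <- circ$p_fill_threshold
      }
    } else if (state$phase == "filling") {
      V_new <- solve_cavity_volume(geom, state$p_endo, V, q, land, passive,
                                   active, n_quad)
      state <- filling_step(state, V_new - V, circ)
      V <- V_new
      state$v_endo <- V
      if (V >= (1 - 0.01) * V0) done <- TRUE
    }

    r_i <- (3 * V / (4 * pi))^(1 / 3)
    r_o <- (r_i^3 + geom$r_epi0^3 - geom$r_endo0^3)^(1 / 3)
    rec$t[s] <- t; rec$phase[s] <- state$phase
    rec$p_endo[s] <- state$p_endo; rec$p_art[s] <- state$p_art
    rec$v_endo[s] <- V; rec$sigma_0[s] <- sigma0; rec$lambda[s] <- lam
    rec$wall_thickness[s] <- r_o - r_i
    rec$cavity_length[s] <- geom$l0 * r_i / geom$r_endo0
    rec$t_act[s] <- active_tension(q, lam, land); rec$ca_i[s] <- ca_fn(t)
    n_rec <- s
    if (done) break
  }

  trace <- tibble::as_tibble(lapply(rec, function(v) v[seq_len(n_rec)]))
  all_phases <- c("initiation", "ivc", "ejection", "ivr", "filling")
  missing_ph <- setdiff(all_phases, unique(trace$phase))
  if (length(missing_ph) && strict) {
    abort(paste0("cardiac cycle stuck: phase '", missing_ph[1], "' never triggered."))
  }
  structure(
    list(
      trace = trace, sigma_0 = sigma0, completed = length(missing_ph) == 0L,
      phases_reached = unique(trace$phase), geom = geom, circ = circ,
      dt = dt, esv_time = esv_time
    ),
    class = "cardiac_cycle"
  )
}

#' Mechanical biomarkers of a simulated cycle
#'
#' Extracts EF, ESP, LFS and WT from a [run_cardiac_cycle()] result. End of
#' ejection is taken from the phase log (last ejection sample), not from
#' pressure heuristics. A cycle that never ejected yields EF = 0, LFS = 0,
#' WT = 0 and ESP = max pressure (the diagnostic no-contraction path). A
#' cycle whose ejection started but whose flow never reversed within the
#' simulated window has no end-systole: it is a non-convergent run and its
#' biomarkers are `NA` (downstream sensitivity analysis masks such runs
#' rather than imputing them).
#'
#' @param cycle a `cardiac_cycle`.
#' @return one-row tibble with `EF`, `ESP`, `LFS`, `WT`, `EDV`, `ESV`,
#'   `stroke_volume`, `completed`.
#' @export
cycle_biomarkers <- function(cycle) {
  tr <- cycle$trace
  edv <- cycle$geom$edv
  esp <- end_systolic_pressure(tr$p_endo)
  ej <- tr[tr$phase == "ejection", ]
  if (nrow(ej) == 0L) {
    return(tibble::tibble(EF = 0, ESP = esp, LFS = 0, WT = 0, EDV = edv,
                          ESV = edv, stroke_volume = 0, completed = FALSE))
  }
  if (!"ivr" %in% tr$phase) {
    # ejection never terminated: no end-systole exists on this run
    return(tibble::tibble(EF = NA_real_, ESP = esp, LFS = NA_real_,
                          WT = NA_real_, EDV = edv, ESV = NA_real_,
                          stroke_volume = NA_real_, completed = FALSE))
  }
  end_ej <- ej[nrow(ej), ]
  esv <- end_ej$v_endo
  tibble::tibble(
    EF = ejection_fraction(edv, esv),
    ESP = esp,
    LFS = longitudinal_fractional_shortening(cycle$geom$l0, end_ej$cavity_length),
    WT = wall_thickening(cycle$geom$r_epi0 - cycle$geom$r_endo0, end_ej$wall_thickness),
    EDV = edv, ESV = esv, stroke_volume = edv - esv,
    completed = cycle$completed
  )
}
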