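#' Circulation parameters
#'
#' Parameters of the five-phase cardiac-cycle state machine: initiation
#' penalties (`inv_cp0`, `inv_cv0` are the inverses `1/Cp0`, `1/Cv0`),
#' isovolumetric penalties (`inv_cp`, `inv_cv`), the two-element Windkessel
#' compliance `compliance` (ml/mmHg) and resistance `resistance`
#' (mmHg ms/ml), the filling decay constant `gamma` (mmHg/ml), the
#' end-diastolic pressure `p0`, the ejection trigger `p_ej` and the
#' relaxation-to-filling threshold `p_fill_threshold` (all mmHg).
#'
#' @param ... named overrides of the shipped defaults.
#' @return list of class `circulation_params`.
#' @export
circulation_params <- function(...) {
  p <- default_params()$circulation
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort(paste("unknown circulation parameter(s):", paste(unknown, collapse = ", ")))
  p[names(ov)] <- ov
  if (p$compliance <= 0 || p$resistance <= 0 || p$gamma <= 0) {
    abort("compliance, resistance and gamma must be positive.")
  }
  if (!(p$p_ej > p$p0 && p$p0 > 0)) abort("need p_ej > p0 > 0.")
  structure(p, class = "circulation_params")
}

#' Circulation state
#'
#' Phase label plus endocardial pressure, arterial pressure, cavity volume,
#' pre-stress and time. Phases advance one-way through
#' initiation -> ivc -> ejection -> ivr -> filling.
#'
#' @param phase one of `"initiation"`, `"ivc"`, `"ejection"`, `"ivr"`,
#'   `"filling"`.
#' @param p_endo,p_art pressures (mmHg).
#' @param v_endo cavity volume (ml, > 0).
#' @param sigma_0 pre-stress (mmHg-equivalent fibre tension; see the
#'   lumped-ventricle driver for the unit convention actually used).
#' @param t time (ms).
#' @return list of class `circulation_state`.
#' @export
circulation_state <- function(phase = "initiation", p_endo = 0, p_art = 0,
                              v_endo = 1, sigma_0 = 0, t = 0) {
  phase <- match.arg(phase, c("initiation", "ivc", "ejection", "ivr", "filling"))
  if (v_endo <= 0) abort("v_endo must be positive.")
  structure(list(phase = phase, p_endo = p_endo, p_art = p_art,
                 v_endo = v_endo, sigma_0 = sigma_0, t = t),
            class = "circulation_state")
}

#' Pre-stress penalty update (initiation phase)
#'
#' Per-step increment rule
#' `sigma_0 <- sigma_0 + (1/Cp0) dV + (1/Cv0) dV/dt`, used during
#' initiation to find the fibre pre-stress that holds the cavity at its
#' end-diastolic volume while the pressure ramps up; the pre-stress is
#' frozen at phase exit.
#'
#' @param state a [circulation_state()] in phase `initiation`.
#' @param dV volume increment over the step (ml).
#' @param dt step duration (ms, > 0).
#' @param p a [circulation_params()].
#' @return updated [circulation_state()].
#' @export
prestress_update <- function(state, dV, dt, p) {
  if (state$phase != "initiation") abort("prestress_update applies only during initiation.")
  if (dt <= 0) abort("dt must be positive.")
  state$sigma_0 <- state$sigma_0 + p$inv_cp0 * dV + p$inv_cv0 * (dV / dt)
  state
}

#' Isovolumetric pressure penalty update
#'
#' Per-step increment rule `P_endo <- P_endo - (1/Cp) dV - (1/Cv) dV/dt`:
#' the ventricular pressure correction that counteracts any volume drift
#' during the isovolumetric phases (contraction shrinking the cavity raises
#' the pressure).
#'
#' @inheritParams prestress_update
#' @param state a [circulation_state()] in phase `ivc` or `ivr`.
#' @return updated [circulation_state()].
#' @export
isovolumetric_pressure_update <- function(state, dV, dt, p) {
  if (!state$phase %in% c("ivc", "ivr")) {
    abort("isovolumetric_pressure_update applies only during ivc or ivr.")
  }
  if (dt <= 0) abort("dt must be positive.")
  state$p_endo <- state$p_endo - p$inv_cp * dV - p$inv_cv * (dV / dt)
  state
}

#' Windkessel ejection step (exact-exponential update)
#'
#' Integrates the two-element Windkessel
#' `C dP_art/dt + P_art/R = -dV_endo/dt` over one step with the ventricular
#' outflow `Q = -dV/dt` held constant on the step, using the exact solution
#' `P_art(t+dt) = P_art e^(-dt/RC) + R Q (1 - e^(-dt/RC))`. Unconditionally
#' stable; with zero flow it reduces to the pure RC decay and with constant
#' outflow it relaxes to the asymptote `Q R`.
#'
#' @param state a [circulation_state()] in phase `ejection`.
#' @param dV_dt cavity volume rate (ml/ms; negative during ejection).
#' @param dt step (ms).
#' @param p a [circulation_params()].
#' @return updated [circulation_state()].
#' @export
windkessel_ejection_step <- function(state, dV_dt, dt, p) {
  if (state$phase != "ejection") abort("windkessel_ejection_step applies only during ejection.")
  tau <- p$resistance * p$compliance
  decay <- exp(-dt / tau)
  Q <- -dV_dt
  state$p_art <- state$p_art * decay + p$resistance * Q * (1 - decay)
  state
}

#' Filling-phase pressure decay
#'
#' `P_endo <- P_endo - gamma dV`: integrated over the phase this is exactly
#' `-gamma (V_end - V_start)`, independent of the path.
#'
#' @param state a [circulation_state()] in phase `filling`.
#' @param dV volume increment (ml).
#' @param p a [circulation_params()].
#' @return updated [circulation_state()].
#' @export
filling_step <- function(state, dV, p) {
  if (state$phase != "filling") abort("filling_step applies only during filling.")
  state$p_endo <- state$p_endo - p$gamma * dV
  state
}

#' Phase-transition logic
#'
#' One-way transitions: `ivc -> ejection` when `P_endo > p_ej`;
#' `ejection -> ivr` when the median-smoothed volume rate turns positive
#' (flow reversal); `ivr -> filling` when `P_endo < p_fill_threshold`;
#' `filling` completes when the volume recovers the end-diastolic volume.
#' Flow reversal uses a median over the last `smoothing_window` rates to
#' avoid chatter from the penalty stabilisation terms.
#'
#' @param state a [circulation_state()].
#' @param p a [circulation_params()].
#' @param flow_history numeric vector of recent `dV/dt` values (most recent
#'   last), used only in the ejection phase.
#' @param edv end-diastolic volume (ml), used only in the filling phase.
#' @return the (possibly advanced) [circulation_state()]; when filling
#'   completes the phase string becomes `"done"` in the `complete` field.
#' @export
advance_phase <- function(state, p, flow_history = numeric(), edv = NA_real_) {
  if (state$phase == "ivc" && state$p_endo > p$p_ej) {
    state$phase <- "ejection"
    state$p_art <- max(state$p_art, p$p_ej)
  } else if (state$phase == "ejection") {
    w <- p$smoothing_window
    if (length(flow_history) >= w) {
      vdot <- median(tail(flow_history, w))
      if (vdot > 0) state$phase <- "ivr"
    }
  } else if (state$phase == "ivr" && state$p_endo < p$p_fill_threshold) {
    state$phase <- "filling"
  } else if (state$phase == "filling" && is.finite(edv) && state$v_endo >= edv) {
    state$complete <- TRUE
  }
  state
}
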