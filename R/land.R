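#' Land model parameters
#'
#' Parameters of the six-state human active-contraction (Land) model.
#' Primary constants come from the shipped parameter file; the derived
#' transition rates are computed here from the duty ratios:
#' `k_wu = k_uw (1/r_w - 1) - k_ws`, `k_su = k_ws r_w (1/r_s - 1)`,
#' the blocked-site forward rate
#' `K_u = ku trpn50^n_tm / (1 - r_s - (1 - r_s) r_w)` (with `k_u = ku` the
#' backward rate, a convention recorded in the parameter file), the
#' distortion gains `A_s = A_w = tot_a r_s / ((1 - r_s) r_w + r_s)` and the
#' distortion decay rates `c_w = phi_a k_uw (1 - r_w)/r_w`,
#' `c_s = phi_a k_ws (1 - r_s) r_w / r_s`.
#'
#' @param ... named overrides of primary constants (e.g. `t_ref`, in Pa).
#' @return list of class `land_params` containing both primary and derived
#'   constants.
#' @export
land_params <- function(...) {
  p <- default_params()$land
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort(paste("unknown Land parameter(s):", paste(unknown, collapse = ", ")))
  p[names(ov)] <- ov
  with(p, {
    if (any(c(k_trpn, n_trpn, ca_t50_ref, ku, n_tm, k_uw, k_ws, t_ref) <= 0)) {
      abort("Land rates, exponents and t_ref must be positive.")
    }
  })
  p$k_wu <- p$k_uw * (1 / p$r_w - 1) - p$k_ws
  p$k_su <- p$k_ws * p$r_w * (1 / p$r_s - 1)
  p$K_u <- p$ku * p$trpn50^p$n_tm / (1 - p$r_s - (1 - p$r_s) * p$r_w)
  p$A_w <- p$tot_a * p$r_s / ((1 - p$r_s) * p$r_w + p$r_s)
  p$A_s <- p$A_w
  p$c_w <- p$phi_a * p$k_uw * (1 - p$r_w) / p$r_w
  p$c_s <- p$phi_a * p$k_ws * (1 - p$r_s) * p$r_w / p$r_s
  structure(p, class = "land_params")
}

#' Land contraction state
#'
#' The six state variables of the active-contraction model: post- and
#' pre-powerstroke crossbridge fractions `S` and `W`, bound-troponin
#' fraction `CaTRPN`, blocked-site fraction `B`, and the two distortions
#' `zeta_s`, `zeta_w`. The resting state has all sites blocked and a small
#' bound-troponin fraction.
#'
#' @param S,W,CaTRPN,B,zeta_s,zeta_w state values.
#' @return named numeric vector of class `land_state`.
#' @export
land_state <- function(S = 0, W = 0, CaTRPN = 0.02, B = 1, zeta_s = 0, zeta_w = 0) {
  q <- c(S = S, W = W, CaTRPN = CaTRPN, B = B, zeta_s = zeta_s, zeta_w = zeta_w)
  if (any(q[c("S", "W", "CaTRPN", "B")] < -1e-12) ||
      any(q[c("S", "W", "CaTRPN", "B")] > 1 + 1e-12)) {
    abort("S, W, CaTRPN and B must lie in [0, 1].")
  }
  if (q["S"] + q["W"] + q["B"] > 1 + 1e-9) {
    abort("occupancies must satisfy S + W + B <= 1.")
  }
  structure(q, class = c("land_state", "numeric"))
}

#' Post-powerstroke distortion-dependent unbinding rate
#'
#' Piecewise rate `gamma_su`: `gamma_s (-zeta_s - 1)` when `zeta_s + 1 < 0`,
#' `gamma_s zeta_s` when `zeta_s + 1 > 1`, and zero otherwise (including the
#' gap `zeta_s` in `(-1, 0)`, exactly as printed in the source model).
#'
#' @param zeta_s post-powerstroke distortion.
#' @param gamma_s rate constant (1/ms).
#' @return rate (1/ms).
#' @export
gamma_su <- function(zeta_s, gamma_s) {
  ifelse(zeta_s + 1 < 0, gamma_s * (-zeta_s - 1),
         ifelse(zeta_s + 1 > 1, gamma_s * zeta_s, 0))
}

#' Length-dependent calcium sensitivity
#'
#' Half-activation calcium `CaT50 = CaT50_ref + beta_1 (min(lam_f, 1.2) - 1)`;
#' the stretch dependence saturates at `lam_f = 1.2`.
#'
#' @param lam_f fibre stretch (> 0).
#' @param p a [land_params()].
#' @return concentration (uM).
#' @export
ca_t50 <- function(lam_f, p = land_params()) {
  if (any(lam_f <= 0)) abort("lam_f must be positive.")
  p$ca_t50_ref + p$beta_1 * (pmin(lam_f, 1.2) - 1)
}

#' Right-hand side of the Land ODE system
#'
#' Time derivatives of the six contraction states given intracellular
#' calcium, fibre stretch and stretch rate:
#' \itemize{
#' \item `dS = k_ws W - k_su S - gamma_su(zeta_s) S`
#' \item `dW = k_uw U - k_wu W - k_ws W - gamma_w |zeta_w| W`, `U = 1-B-S-W`
#' \item `dCaTRPN = k_trpn [ (Ca/CaT50)^n_trpn (1 - CaTRPN) - CaTRPN ]`
#' \item `dB = K_u CaTRPN^(-n_tm/2) U - k_u CaTRPN^(n_tm/2) B`
#' \item `dzeta_s = A_s lam_dot - c_s zeta_s`; `dzeta_w = A_w lam_dot - c_w zeta_w`
#' }
#' `CaTRPN` is floored at `p$catrpn_floor` inside the negative power so the
#' blocking rate cannot blow up near zero occupancy.
#'
#' @param q named state vector (see [land_state()]).
#' @param ca_i intracellular calcium (uM, > 0).
#' @param lam_f fibre stretch.
#' @param dlam_f_dt fibre stretch rate (1/ms).
#' @param p a [land_params()].
#' @return named numeric vector of six time derivatives (1/ms).
#' @export
land_rhs <- function(q, ca_i, lam_f, dlam_f_dt, p = land_params()) {
  S <- q[["S"]]; W <- q[["W"]]; CaTRPN <- q[["CaTRPN"]]; B <- q[["B"]]
  zs <- q[["zeta_s"]]; zw <- q[["zeta_w"]]
  U <- 1 - B - S - W
  ct <- max(CaTRPN, p$catrpn_floor)
  g_su <- gamma_su(zs, p$gamma_s)
  g_wu <- p$gamma_w * abs(zw)
  cat50 <- ca_t50(lam_f, p)
  c(
    S = p$k_ws * W - p$k_su * S - g_su * S,
    W = p$k_uw * U - p$k_wu * W - p$k_ws * W - g_wu * W,
    CaTRPN = p$k_trpn * ((ca_i / cat50)^p$n_trpn * (1 - CaTRPN) - CaTRPN),
    B = p$K_u * ct^(-p$n_tm / 2) * U - p$ku * ct^(p$n_tm / 2) * B,
    zeta_s = p$A_s * dlam_f_dt - p$c_s * zs,
    zeta_w = p$A_w * dlam_f_dt - p$c_w * zw
  )
}

#' Length-dependence factor of active tension
#'
#' The piecewise-linear factor `h-hat(lam_f)`:
#' zero below `(1.87 beta_0 - 1)/(2 beta_0)`, then
#' `1 + beta_0 (2 lam_f - 1.87)` up to 0.87, then `1 + beta_0 (lam_f - 1)`
#' up to 1.2, and constant `1 + 0.2 beta_0` beyond. Continuous on
#' `(0, Inf)` for any `beta_0 > 0`.
#'
#' @param lam_f fibre stretch (> 0), vectorised.
#' @param beta_0 positive length-dependence constant.
#' @return dimensionless factor.
#' @export
h_lambda <- function(lam_f, beta_0) {
  if (!is.finite(beta_0) || beta_0 <= 0) abort("beta_0 must be positive.")
  cut0 <- (1.87 * beta_0 - 1) / (2 * beta_0)
  ifelse(lam_f < cut0, 0,
         ifelse(lam_f < 0.87, 1 + beta_0 * (2 * lam_f - 1.87),
                ifelse(lam_f < 1.2, 1 + beta_0 * (lam_f - 1),
                       1 + 0.2 * beta_0)))
}

#' Active tension in the fibre direction
#'
#' `Tact = h-hat(lam_f) (T_ref / r_s) [ (zeta_s + 1) S + zeta_w W ]`.
#'
#' @param q named state vector.
#' @param lam_f fibre stretch.
#' @param p a [land_params()].
#' @return active tension (Pa).
#' @export
active_tension <- function(q, lam_f, p = land_params()) {
  h_lambda(lam_f, p$beta_0) * (p$t_ref / p$r_s) *
    ((q[["zeta_s"]] + 1) * q[["S"]] + q[["zeta_w"]] * q[["W"]])
}

#' Orthotropic active stress parameters
#'
#' Weights of the active stress tensor in the sheet (`kort1`) and normal
#' (`kort2`) directions, plus the fibre pre-stress `sigma0` calibrated in
#' the initiation phase.
#'
#' @param kort1,kort2 non-negative activation weights.
#' @param sigma0 pre-stress (Pa).
#' @return list of class `active_stress_params`.
#' @export
active_stress_params <- function(kort1 = 0, kort2 = 0, sigma0 = 0) {
  if (kort1 < 0 || kort2 < 0) abort("kort1 and kort2 must be non-negative.")
  structure(list(kort1 = kort1, kort2 = kort2, sigma0 = sigma0),
            class = "active_stress_params")
}

#' Active second Piola-Kirchhoff stress
#'
#' Material form of the orthotropic active stress,
#' \deqn{S_{act} = \frac{T_{act} + \sigma_0}{\lambda_f^2} f_0 \otimes f_0
#'   + k_{ort1}\frac{T_{act}}{\lambda_s^2} s_0 \otimes s_0
#'   + k_{ort2}\frac{T_{act}}{\lambda_n^2} \bar n_0 \otimes \bar n_0,}
#' equal to the pull-back `J F^-1 sigma_act F^-T` of the spatial active
#' stress; the pre-stress acts only in the fibre direction.
#'
#' @param Tact active tension (Pa).
#' @param def a [deformation_state()].
#' @param frame a [fibre_frame()].
#' @param inv [compute_invariants()] of `def$C` and `frame` (recomputed if
#'   `NULL`).
#' @param ap an [active_stress_params()].
#' @return symmetric 3x3 stress tensor (Pa).
#' @export
active_pk2 <- function(Tact, def, frame, inv = NULL, ap = active_stress_params()) {
  if (is.null(inv)) inv <- compute_invariants(def$C, frame)
  (Tact + ap$sigma0) / inv$lam_f^2 * outer3(frame$f0) +
    ap$kort1 * Tact / inv$lam_s^2 * outer3(frame$s0) +
    ap$kort2 * Tact / inv$lam_n^2 * outer3(frame$n0)
}

#' Algebraic steady state of the Land model
#'
#' Fixed point of the contraction ODEs at clamped calcium and stretch
#' (`lam_dot = 0`). The distortions vanish; `CaTRPN` solves its own scalar
#' balance in closed form, and the occupancies `(S, W, B)` then solve a
#' 3x3 linear system obtained by setting the `S`, `W` and `B` rows of the
#' right-hand side to zero. This is used as the independent oracle for the
#' ODE-integrated steady state.
#'
#' @param ca_i clamped calcium (uM).
#' @param lam_f clamped fibre stretch.
#' @param p a [land_params()].
#' @return named state vector at equilibrium.
#' @export
land_steady_state <- function(ca_i, lam_f = 1, p = land_params()) {
  r <- (ca_i / ca_t50(lam_f, p))^p$n_trpn
  ct <- max(r / (1 + r), p$catrpn_floor)
  kb_f <- p$K_u * ct^(-p$n_tm / 2)   # U -> B
  kb_b <- p$ku * ct^(p$n_tm / 2)     # B -> U
  # unknowns x = (S, W, B); U = 1 - S - W - B
  A <- rbind(
    c(-p$k_su, p$k_ws, 0),                                     # dS = 0
    c(-p$k_uw, -(p$k_uw + p$k_wu + p$k_ws), -p$k_uw),          # dW = 0 (U expanded)
    c(-kb_f, -kb_f, -(kb_f + kb_b))                            # dB = 0 (U expanded)
  )
  b <- c(0, -p$k_uw, -kb_f)
  x <- solve(A, b)
  land_state(S = x[1], W = x[2], CaTRPN = ct, B = x[3], zeta_s = 0, zeta_w = 0)
}

#' Integrate the Land ODEs at prescribed calcium and stretch
#'
#' Adaptive stiff integration (lsoda) of [land_rhs()] with user-supplied
#' calcium and stretch trajectories.
#'
#' @param q0 initial state ([land_state()]).
#' @param times output times (ms).
#' @param ca_fn function of time returning calcium (uM).
#' @param lam_fn,dlam_fn functions of time returning stretch and stretch
#'   rate (defaults: clamped at 1 and 0).
#' @param p a [land_params()].
#' @param rtol,atol integration tolerances.
#' @return tibble with columns `t` and the six states.
#' @export
integrate_land <- function(q0, times, ca_fn,
                           lam_fn = function(t) 1,
                           dlam_fn = function(t) 0,
                           p = land_params(), rtol = 1e-6, atol = 1e-9) {
  deriv <- function(t, y, parms) {
    list(land_rhs(y, ca_fn(t), lam_fn(t), dlam_fn(t), p))
  }
  out <- deSolve::lsoda(unclass(q0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  res <- tibble::as_tibble(as.data.frame(out))
  names(res)[1] <- "t"
  res
}
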