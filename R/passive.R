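#' Holzapfel-Ogden material parameters
#'
#' Parameters of the quasi-incompressible orthotropic Holzapfel-Ogden
#' strain energy. `K`, `a`, `af`, `as`, `afs` carry stress units (Pa
#' internally); `b`, `bf`, `bs`, `bfs` are dimensionless. Defaults are read
#' from the shipped parameter file (`inst/extdata/default_params.yaml`),
#' which records their provenance: the classic shear-data fit of the
#' original orthotropic myocardium law, with the sheet-direction linear
#' parameter `as` and the bulk modulus `K` set to the framework's baseline
#' values (2564 Pa and 3333 kPa).
#'
#' @param ... named overrides of any parameter (values in Pa for the
#'   stress-dimension parameters).
#' @return list of class `ho_params`.
#' @examples
#' p <- ho_params()
#' p$as  # 2564 Pa
#' @export
ho_params <- function(...) {
  p <- default_params()$passive
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort(paste("unknown HO parameter(s):", paste(unknown, collapse = ", ")))
  p[names(ov)] <- ov
  if (any(unlist(p) <= 0)) abort("all Holzapfel-Ogden parameters must be positive.")
  structure(p, class = "ho_params")
}

# positive part <x>+ = (x + |x|)/2
pos_part <- function(x) (x + abs(x)) / 2

#' Passive strain energy density
#'
#' Quasi-incompressible orthotropic strain energy
#' \deqn{\psi = \frac{K}{2}(J-1)^2
#'   + \frac{a}{2b}\left[e^{b(\bar I_1 - 3)} - 1\right]
#'   + \sum_{i=f,s} \frac{a_i}{2b_i}\left[e^{b_i \langle \bar I_{4i}-1\rangle_+^2} - 1\right]
#'   + \frac{a_{fs}}{2b_{fs}}\left[e^{b_{fs}\bar I_{8fs}^2} - 1\right],}
#' with isochoric invariants computed from \eqn{\bar C = J^{-2/3} C} and the
#' positive-part switch disabling the fibre/sheet terms under compression
#' (\eqn{\bar I_{4i} < 1}).
#'
#' @param def a [deformation_state()].
#' @param frame a [fibre_frame()].
#' @param p an [ho_params()].
#' @return scalar energy density (Pa).
#' @export
strain_energy <- function(def, frame, p = ho_params()) {
  stopifnot(inherits(def, "deformation_state"))
  ibar <- compute_invariants(def$C_bar, frame)
  e4f <- pos_part(ibar$I4f - 1)
  e4s <- pos_part(ibar$I4s - 1)
  p$K / 2 * (def$J - 1)^2 +
    p$a / (2 * p$b) * (exp(p$b * (ibar$I1 - 3)) - 1) +
    p$af / (2 * p$bf) * (exp(p$bf * e4f^2) - 1) +
    p$as / (2 * p$bs) * (exp(p$bs * e4s^2) - 1) +
    p$afs / (2 * p$bfs) * (exp(p$bfs * ibar$I8fs^2) - 1)
}

#' Passive second Piola-Kirchhoff stress
#'
#' Closed-form derivative `S_pas = 2 dpsi/dC` of [strain_energy()]:
#' volumetric term `K(J-1) J C^-1` plus isochoric isotropic, fibre, sheet
#' and fibre-sheet shear terms, each deviatorically projected
#' (`X - (I_X/3) C^-1` structure). The exponentials use the isochoric
#' (barred) invariants throughout, consistent with the strain energy; the
#' implementation is verified against a finite-difference derivative of
#' [strain_energy()] in the test suite.
#'
#' @inheritParams strain_energy
#' @return symmetric 3x3 stress tensor (Pa).
#' @export
passive_pk2 <- function(def, frame, p = ho_params()) {
  stopifnot(inherits(def, "deformation_state"))
  C <- def$C
  J <- def$J
  Cinv <- solve(C)
  Cinv <- (Cinv + t(Cinv)) / 2
  iv <- compute_invariants(C, frame)       # un-barred invariants
  ibar <- compute_invariants(def$C_bar, frame)
  Jm23 <- J^(-2 / 3)
  f0 <- frame$f0; s0 <- frame$s0
  I3 <- diag(3)

  S <- p$K * (J - 1) * J * Cinv +
    Jm23 * p$a * exp(p$b * (ibar$I1 - 3)) * (I3 - iv$I1 / 3 * Cinv)

  e4f <- pos_part(ibar$I4f - 1)
  if (e4f > 0) {
    S <- S + 2 * Jm23 * p$af * e4f * exp(p$bf * e4f^2) *
      (outer3(f0) - iv$I4f / 3 * Cinv)
  }
  e4s <- pos_part(ibar$I4s - 1)
  if (e4s > 0) {
    S <- S + 2 * Jm23 * p$as * e4s * exp(p$bs * e4s^2) *
      (outer3(s0) - iv$I4s / 3 * Cinv)
  }
  S <- S + 2 * Jm23 * p$afs * ibar$I8fs * exp(p$bfs * ibar$I8fs^2) *
    ((outer3(f0, s0) + outer3(s0, f0)) / 2 - iv$I8fs / 3 * Cinv)
  (S + t(S)) / 2
}

#' Cauchy stress push-forward
#'
#' Pushes a second Piola-Kirchhoff stress to the spatial (Cauchy) stress,
#' `sigma = J^-1 F S F^T`.
#'
#' @param S 3x3 second Piola-Kirchhoff stress.
#' @param def a [deformation_state()].
#' @return 3x3 Cauchy stress.
#' @export
push_forward_stress <- function(S, def) {
  (def$F %*% S %*% t(def$F)) / def$J
}
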