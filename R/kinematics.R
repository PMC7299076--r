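#' Orthonormal myocardial fibre frame
#'
#' Constructs the right-handed orthonormal triad of material directions
#' used throughout cardiac continuum mechanics: `f0` (fibre), `s0` (sheet)
#' and `n0` (normal to the fibre-sheet plane, `n0 = f0 x s0`). Inputs are
#' re-orthonormalised by Gram-Schmidt so that frames built from slightly
#' inexact vectors still satisfy the orthonormality invariants to machine
#' precision.
#'
#' @param f0 fibre direction (length-3 numeric, need not be unit).
#' @param s0 sheet direction (length-3 numeric); its component along `f0`
#'   is removed.
#' @return an object of class `fibre_frame`: list with unit vectors
#'   `f0`, `s0`, `n0`.
#' @examples
#' fr <- fibre_frame(c(1, 0, 0), c(0, 1, 0))
#' fr$n0  # c(0, 0, 1)
#' @export
fibre_frame <- function(f0, s0) {
  f0 <- as.numeric(f0); s0 <- as.numeric(s0)
  if (length(f0) != 3L || length(s0) != 3L) {
    abort("f0 and s0 must be length-3 numeric vectors.")
  }
  nf <- sqrt(sum(f0^2))
  if (nf < 1e-14) abort("f0 has zero length.")
  f0 <- f0 / nf
  s0 <- s0 - sum(s0 * f0) * f0
  ns <- sqrt(sum(s0^2))
  if (ns < 1e-14) abort("s0 is parallel to f0; cannot build a frame.")
  s0 <- s0 / ns
  n0 <- c(
    f0[2] * s0[3] - f0[3] * s0[2],
    f0[3] * s0[1] - f0[1] * s0[3],
    f0[1] * s0[2] - f0[2] * s0[1]
  )
  structure(list(f0 = f0, s0 = s0, n0 = n0), class = "fibre_frame")
}

#' Validate a fibre frame
#'
#' Checks unit norms, pairwise orthogonality and right-handedness
#' (`f0 x s0 = n0`) to within `tol`.
#'
#' @param frame a [fibre_frame()].
#' @param tol numeric tolerance (default `1e-12`).
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_fibre_frame <- function(frame, tol = 1e-12) {
  stopifnot(inherits(frame, "fibre_frame"))
  v <- with(frame, list(f0 = f0, s0 = s0, n0 = n0))
  for (nm in names(v)) {
    if (abs(sum(v[[nm]]^2) - 1) > tol) abort(paste0(nm, " is not unit length."))
  }
  if (abs(sum(v$f0 * v$s0)) > tol || abs(sum(v$f0 * v$n0)) > tol ||
      abs(sum(v$s0 * v$n0)) > tol) {
    abort("frame vectors are not pairwise orthogonal.")
  }
  cr <- c(
    v$f0[2] * v$s0[3] - v$f0[3] * v$s0[2],
    v$f0[3] * v$s0[1] - v$f0[1] * v$s0[3],
    v$f0[1] * v$s0[2] - v$f0[2] * v$s0[1]
  )
  if (max(abs(cr - v$n0)) > tol) abort("frame is not right-handed (f0 x s0 != n0).")
  invisible(TRUE)
}

#' Deformation state from a deformation gradient
#'
#' Wraps a deformation gradient `F` together with the derived kinematic
#' quantities used by the constitutive laws: `J = det F`, the right
#' Cauchy-Green tensor `C = F^T F`, and its isochoric (unimodular) part
#' `C_bar = J^(-2/3) C` with `det(C_bar) = 1`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @return object of class `deformation_state` with fields `F`, `J`, `C`,
#'   `C_bar`.
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L))) abort("F must be a 3x3 matrix.")
  J <- det(F)
  if (!is.finite(J) || J <= 0) abort("det(F) must be positive.")
  C <- crossprod(F)          # F^T F, symmetric by construction
  C <- (C + t(C)) / 2
  structure(
    list(F = F, J = J, C = C, C_bar = J^(-2 / 3) * C),
    class = "deformation_state"
  )
}

#' Strain invariants and directional stretches
#'
#' Computes the invariants of the right Cauchy-Green tensor used by the
#' orthotropic strain energy, `I1 = tr C`, `I4f = f0.(C f0)`,
#' `I4s = s0.(C s0)`, `I8fs = (f0.(C s0) + s0.(C f0))/2`, and the stretches
#' along the three material directions, `lam_f = sqrt(I4f)` etc. The stretch
#' is the square root of the corresponding fourth invariant, so that all
#' stretches equal 1 in the reference configuration.
#'
#' @param C 3x3 symmetric positive-definite tensor (right Cauchy-Green).
#' @param frame a [fibre_frame()].
#' @return list of class `strain_invariants` with `I1`, `I4f`, `I4s`,
#'   `I8fs`, `lam_f`, `lam_s`, `lam_n`.
#' @examples
#' fr <- fibre_frame(c(1, 0, 0), c(0, 1, 0))
#' compute_invariants(diag(3), fr)$I1  # 3
#' @export
compute_invariants <- function(C, frame) {
  C <- as.matrix(C)
  if (!all(dim(C) == c(3L, 3L))) abort("C must be 3x3.")
  if (max(abs(C - t(C))) > 1e-10) abort("C must be symmetric.")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("C must be symmetric positive definite.")
  f0 <- frame$f0; s0 <- frame$s0; n0 <- frame$n0
  Cf <- C %*% f0; Cs <- C %*% s0; Cn <- C %*% n0
  I4f <- sum(f0 * Cf)
  I4s <- sum(s0 * Cs)
  I4n <- sum(n0 * Cn)
  structure(
    list(
      I1 = sum(diag(C)),
      I4f = I4f,
      I4s = I4s,
      I8fs = (sum(f0 * Cs) + sum(s0 * Cf)) / 2,
      lam_f = sqrt(I4f),
      lam_s = sqrt(I4s),
      lam_n = sqrt(I4n)
    ),
    class = "strain_invariants"
  )
}

#' Transmural rule-based fibre frame
#'
#' Linear transmural fibre rule: the fibre direction lies in the
#' circumferential-longitudinal plane and makes an angle
#' `phi * wall_coordinate` with the basal (circumferential) plane -- zero at
#' mid-wall, `-phi` at the endocardium and `+phi` at the epicardium. The
#' sheet direction is transmural (parallel to the wall normal) and constant
#' through the wall.
#'
#' The local wall coordinate system is given by `circ` (circumferential,
#' in the basal plane), `radial` (transmural wall normal) and the
#' apico-basal direction implied by their cross product.
#'
#' @param phi maximal fibre angle in degrees, in `[0, 90]`.
#' @param wall_coordinate transmural coordinate in `[-1, 1]`: -1 endocardium,
#'   0 mid-wall, +1 epicardium.
#' @param circ,radial local circumferential and transmural unit directions
#'   (defaults: x and z axes).
#' @return a [fibre_frame()].
#' @export
build_fibre_field <- function(phi, wall_coordinate,
                              circ = c(1, 0, 0), radial = c(0, 0, 1)) {
  if (!is.finite(phi) || phi < 0 || phi > 90) {
    abort("phi must lie in [0, 90] degrees.")
  }
  if (abs(wall_coordinate) > 1 + 1e-12) {
    abort("wall_coordinate must lie in [-1, 1].")
  }
  circ <- circ / sqrt(sum(circ^2))
  radial <- radial - sum(radial * circ) * circ
  radial <- radial / sqrt(sum(radial^2))
  long <- c(
    radial[2] * circ[3] - radial[3] * circ[2],
    radial[3] * circ[1] - radial[1] * circ[3],
    radial[1] * circ[2] - radial[2] * circ[1]
  )
  alpha <- phi * wall_coordinate * pi / 180
  f0 <- cos(alpha) * circ + sin(alpha) * long
  fibre_frame(f0, radial)
}

#' Isochoric extension along the fibre direction
#'
#' The volume-preserving uniaxial stretch
#' `F = lam^(-1/2) I + (lam - lam^(-1/2)) f0 (x) f0`, which stretches the
#' fibre direction by `lam` and contracts the two transverse directions by
#' `lam^(-1/2)`, so `det F = 1`.
#'
#' @param lam fibre stretch, `> 0`.
#' @param f0 unit fibre direction.
#' @return a [deformation_state()].
#' @examples
#' d <- isochoric_fibre_extension(2, c(1, 0, 0))
#' d$J  # 1
#' @export
isochoric_fibre_extension <- function(lam, f0) {
  if (!is.finite(lam) || lam <= 0) abort("lam must be positive.")
  f0 <- f0 / sqrt(sum(f0^2))
  F <- lam^(-1 / 2) * diag(3) + (lam - lam^(-1 / 2)) * tcrossprod(f0)
  deformation_state(F)
}

# outer product helper used by the stress tensors
outer3 <- function(a, b = a) tcrossprod(a, b)
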