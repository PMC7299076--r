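# shared generators for property-style tests (all seeded by the caller)

random_spd <- function(scale = 0.3) {
  A <- matrix(rnorm(9, sd = scale), 3, 3)
  diag(3) + crossprod(A)
}

random_frame <- function() {
  repeat {
    f <- rnorm(3); s <- rnorm(3)
    if (sqrt(sum(f^2)) > 1e-3 && abs(sum(f * s)) < 0.95 * sqrt(sum(f^2) * sum(s^2))) {
      return(fibre_frame(f, s))
    }
  }
}

random_deformation <- function(strain = 0.1) {
  repeat {
    F <- diag(3) + matrix(rnorm(9, sd = strain), 3, 3)
    if (det(F) > 0.3) return(deformation_state(F))
  }
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# strain energy as a bare function of C, for finite-difference stress oracles
psi_of_C <- function(C, frame, p) {
  J <- sqrt(det(C))
  def <- structure(list(F = NULL, J = J, C = C, C_bar = J^(-2 / 3) * C),
                   class = "deformation_state")
  strain_energy(def, frame, p)
}

# random state kept away from the I4 = 1 kinks of the positive-part terms,
# where the strain energy is not differentiable and an FD oracle is invalid
random_deformation_smooth <- function(strain = 0.08, margin = 5e-3) {
  repeat {
    def <- random_deformation(strain)
    fr <- random_frame()
    ib <- compute_invariants(def$C_bar, fr)
    if (abs(ib$I4f - 1) > margin && abs(ib$I4s - 1) > margin) {
      return(list(def = def, frame = fr))
    }
  }
}

# central finite-difference second Piola-Kirchhoff stress, S = 2 dpsi/dC
fd_pk2 <- function(C, frame, p, eps = 1e-6) {
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in i:3) {
    E <- matrix(0, 3, 3)
    E[i, j] <- eps; E[j, i] <- eps   # symmetric perturbation (diag: once)
    d <- (psi_of_C(C + E, frame, p) - psi_of_C(C - E, frame, p)) / (2 * eps)
    # d(psi)/d(eps) = S_ij for i != j (both entries move); S_ii/2 on the diagonal
    S[i, j] <- S[j, i] <- if (i == j) 2 * d else d
  }
  S
}
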