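#' Conductivity parameters
#'
#' Orthotropic monodomain diffusivities (cm^2/ms) along fibre, sheet and
#' normal directions, plus surface-to-volume ratio `chi` (1/cm) and
#' membrane capacitance `cm` (uF/cm^2). The defaults satisfy
#' `sigma_f >= sigma_s >= sigma_n > 0`.
#'
#' @param ... named overrides.
#' @return list of class `conductivity_params`.
#' @export
conductivity_params <- function(...) {
  p <- default_params()$propagation
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) abort(paste("unknown conductivity parameter(s):", paste(unknown, collapse = ", ")))
  p[names(ov)] <- ov
  if (!(p$sigma_f >= p$sigma_s && p$sigma_s >= p$sigma_n && p$sigma_n > 0)) {
    abort("diffusivities must satisfy sigma_f >= sigma_s >= sigma_n > 0.")
  }
  structure(p, class = "conductivity_params")
}

#' Reference-configuration conductivity tensor
#'
#' `D0 = sigma_f f0(x)f0 + sigma_s s0(x)s0 + sigma_n n0(x)n0`; its
#' eigenvalues are exactly the three diffusivities.
#'
#' @param cp a [conductivity_params()].
#' @param frame a [fibre_frame()].
#' @return symmetric 3x3 tensor (cm^2/ms).
#' @export
conductivity_reference <- function(cp, frame) {
  cp$sigma_f * outer3(frame$f0) +
    cp$sigma_s * outer3(frame$s0) +
    cp$sigma_n * outer3(frame$n0)
}

#' Deformation-dependent conductivity (pulled back)
#'
#' With conductivities measured in the spatial configuration, the tensor in
#' the reference configuration is the pull-back
#' `J [sigma_f/lam_f^2 f0(x)f0 + sigma_s/lam_s^2 s0(x)s0 + sigma_n/lam_n^2 n0(x)n0]`;
#' under an isochoric fibre extension by `lam` the fibre coefficient is
#' reduced by exactly `lam^2`.
#'
#' @param cp a [conductivity_params()].
#' @param def a [deformation_state()].
#' @param frame a [fibre_frame()].
#' @param inv invariants of `def$C` (recomputed when `NULL`).
#' @return symmetric 3x3 tensor (cm^2/ms).
#' @export
conductivity_deformed <- function(cp, def, frame, inv = NULL) {
  if (is.null(inv)) inv <- compute_invariants(def$C, frame)
  def$J * (cp$sigma_f / inv$lam_f^2 * outer3(frame$f0) +
             cp$sigma_s / inv$lam_s^2 * outer3(frame$s0) +
             cp$sigma_n / inv$lam_n^2 * outer3(frame$n0))
}

#' Stretch-activated current
#'
#' `I_SAC = g <lam_f - 1>+ (V - E)`: active only under fibre stretch
#' (`lam_f > 1`), zero at the reversal potential, and zero by default since
#' the framework sets `g = 0`.
#'
#' @param V transmembrane potential (mV), vectorised.
#' @param lam_f fibre stretch.
#' @param p list with `g` (conductance) and `e_rev` (mV); default from the
#'   shipped parameters.
#' @return current density.
#' @export
sac_current <- function(V, lam_f, p = default_params()$sac) {
  if (p$g < 0) abort("SAC conductance must be non-negative.")
  p$g * pos_part(lam_f - 1) * (V - p$e_rev)
}

#' Uniform grid for monodomain simulations
#'
#' A 1D cable or small structured 3D box with spacing `dx` (cm) and
#' zero-flux (Neumann) boundaries. Node indexing is 0-based in user-facing
#' arguments.
#'
#' @param n integer vector of grid sizes: length 1 (cable) or 3 (box).
#' @param dx grid spacing (cm).
#' @return list of class `em_grid` with `n`, `dx`, `n_nodes`.
#' @export
em_grid <- function(n, dx) {
  n <- as.integer(n)
  if (!length(n) %in% c(1L, 3L) || any(n < 2L)) {
    abort("n must be one (cable) or three (box) integers >= 2.")
  }
  if (dx <= 0) abort("dx must be positive.")
  structure(list(n = n, dx = dx, n_nodes = prod(n)), class = "em_grid")
}

# sparse zero-flux Laplacian-like operator: divergence of D grad with a
# spatially uniform (possibly anisotropic, grid-aligned) diffusion tensor.
# For the cable only D[1,1] matters; for a box the diagonal of D is used.
grid_diffusion_operator <- function(grid, D) {
  dx2 <- grid$dx^2
  lap1 <- function(m) {
    # 1D second difference with zero-flux ends, as sparse matrix
    if (m == 1L) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
    i <- c(seq_len(m), seq_len(m - 1L), seq_len(m - 1L) + 1L)
    j <- c(seq_len(m), seq_len(m - 1L) + 1L, seq_len(m - 1L))
    x <- c(c(-1, rep(-2, m - 2L), -1), rep(1, 2L * (m - 1L)))
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, m))
  }
  if (length(grid$n) == 1L) {
    return(D[1, 1] / dx2 * lap1(grid$n))
  }
  d <- diag(D)
  Ix <- Matrix::Diagonal(grid$n[1]); Iy <- Matrix::Diagonal(grid$n[2])
  Iz <- Matrix::Diagonal(grid$n[3])
  (d[1] / dx2) * Matrix::kronecker(Iz, Matrix::kronecker(Iy, lap1(grid$n[1]))) +
    (d[2] / dx2) * Matrix::kronecker(Iz, Matrix::kronecker(lap1(grid$n[2]), Ix)) +
    (d[3] / dx2) * Matrix::kronecker(lap1(grid$n[3]), Matrix::kronecker(Iy, Ix))
}

#' Two-variable cubic test reaction
#'
#' A FitzHugh-Nagumo-type membrane surrogate bundled for propagation tests
#' so that wave propagation can be exercised without a full ionic model.
#' Returns `I_ion` (per unit V/ms after the chi*Cm scaling used in
#' [monodomain_step()]) and the recovery-variable rate.
#'
#' @param V potential (dimensionless units for the test reaction).
#' @param w recovery variable.
#' @param a,eps,b,k reaction constants (`a` threshold, `eps` recovery rate,
#'   `b` recovery gain, `k` excitation rate in 1/ms); the defaults sustain
#'   a travelling pulse on a cable at the shipped diffusivities.
#' @return list with `i_ion` and `dw`.
#' @export
fhn_reaction <- function(V, w, a = 0.13, eps = 0.002, b = 2.5, k = 3) {
  list(
    i_ion = -k * (V * (V - a) * (1 - V) - w),  # inward positive convention
    dw = eps * (b * V - w)
  )
}

#' Stimulus protocol
#'
#' Builds an applied-current function `I_app(node_index0, t)` that is
#' non-zero only for the 0-based node indices in `region` during
#' `[t0, t0 + duration)`. The default duration is the framework's 2 ms
#' stimulus.
#'
#' @param region integer vector of 0-based node indices.
#' @param duration stimulus duration (ms).
#' @param amplitude current amplitude.
#' @param t0 stimulus onset (ms).
#' @return function of `(node0, t)` returning the applied current.
#' @export
apply_stimulus <- function(region, duration = 2, amplitude = 1, t0 = 0) {
  if (length(region) == 0L) abort("stimulus region must be non-empty.")
  if (duration <= 0) abort("stimulus duration must be positive.")
  region <- as.integer(region)
  force(amplitude); force(t0)
  function(node0, t) {
    on <- t >= t0 & t < t0 + duration
    ifelse(on & node0 %in% region, amplitude, 0)
  }
}

#' Monodomain simulator on a uniform grid
#'
#' Operator-split semi-implicit integration of the monodomain equation
#' `chi Cm dV/dt = div(D0 grad V) - chi I_ion + chi I_app`: per step, an
#' explicit reaction update (the bundled two-variable test reaction or a
#' user-supplied one) followed by a backward-Euler diffusion solve with a
#' pre-factorised symmetric positive-definite system. Zero-flux boundaries
#' conserve the total potential in the absence of reaction and stimulus.
#'
#' @param grid an [em_grid()].
#' @param D 3x3 conductivity tensor (grid-aligned diagonal is used), e.g.
#'   from [conductivity_reference()].
#' @param dt time step (ms).
#' @param n_steps number of steps.
#' @param V0,w0 initial fields (length `grid$n_nodes`).
#' @param stimulus function `(node0, t)` from [apply_stimulus()], or `NULL`.
#' @param reaction reaction function `(V, w)` returning `i_ion`, `dw`;
#'   `NULL` disables reaction.
#' @param chi_cm product `chi * Cm` scaling the temporal term (reaction
#'   units absorb `chi`).
#' @param record integer stride at which to record V snapshots.
#' @return list of class `monodomain_run`: `t` (recorded times), `V`
#'   (matrix nodes x times), `w` (final recovery field).
#' @export
run_monodomain <- function(grid, D, dt, n_steps, V0 = NULL, w0 = NULL,
                           stimulus = NULL, reaction = fhn_reaction,
                           chi_cm = 1, record = 1L) {
  if (dt <= 0) abort("dt must be positive.")
  nn <- grid$n_nodes
  V <- if (is.null(V0)) numeric(nn) else as.numeric(V0)
  w <- if (is.null(w0)) numeric(nn) else as.numeric(w0)
  if (length(V) != nn || length(w) != nn) abort("fields must match the grid size.")
  L <- grid_diffusion_operator(grid, D)
  A <- Matrix::Diagonal(nn) - (dt / chi_cm) * L
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A))
  nodes0 <- seq_len(nn) - 1L
  keep <- seq(0L, n_steps, by = as.integer(record))
  Vrec <- matrix(NA_real_, nrow = nn, ncol = length(keep))
  trec <- keep * dt
  ki <- 1L
  if (keep[1L] == 0L) { Vrec[, 1L] <- V; ki <- 2L }
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    if (!is.null(reaction)) {
      rx <- reaction(V, w)
      V <- V - dt * rx$i_ion / 1  # reaction pre-scaled; chi absorbed
      w <- w + dt * rx$dw
    }
    if (!is.null(stimulus)) V <- V + dt * stimulus(nodes0, t) / chi_cm
    V <- as.numeric(Matrix::solve(fac, V))
    if (ki <= length(keep) && s == keep[ki]) {
      Vrec[, ki] <- V
      ki <- ki + 1L
    }
  }
  structure(list(t = trec, V = Vrec, w = w, grid = grid, dt = dt),
            class = "monodomain_run")
}

#' Single operator-split monodomain step
#'
#' Convenience wrapper running one step of [run_monodomain()] from given
#' fields; useful for stepping interleaved with other physics.
#'
#' @inheritParams run_monodomain
#' @param t current time (ms), used for the stimulus window.
#' @return list with updated `V` and `w`.
#' @export
monodomain_step <- function(grid, D, dt, V0, w0, t = 0, stimulus = NULL,
                            reaction = fhn_reaction, chi_cm = 1) {
  run <- run_monodomain(grid, D, dt, 1L, V0 = V0, w0 = w0,
                        stimulus = if (is.null(stimulus)) NULL else {
                          function(node0, tt) stimulus(node0, t + tt)
                        },
                        reaction = reaction, chi_cm = chi_cm, record = 1L)
  list(V = run$V[, ncol(run$V)], w = run$w)
}

#' Conduction velocity on a cable
#'
#' Measures the wavefront speed between two probe nodes from activation
#' times (first upward crossing of `threshold`).
#'
#' @param run a `monodomain_run` on a cable.
#' @param probe1,probe2 0-based probe node indices.
#' @param threshold activation threshold.
#' @return speed in cm/ms.
#' @export
conduction_velocity <- function(run, probe1, probe2, threshold = 0.5) {
  act_time <- function(node0) {
    v <- run$V[node0 + 1L, ]
    idx <- which(v >= threshold)
    if (!length(idx)) return(NA_real_)
    i <- idx[1L]
    if (i == 1L) return(run$t[1L])
    # linear interpolation of the crossing
    t0 <- run$t[i - 1L]; t1 <- run$t[i]
    v0 <- v[i - 1L]; v1 <- v[i]
    t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
  }
  t1 <- act_time(probe1); t2 <- act_time(probe2)
  if (is.na(t1) || is.na(t2) || t2 == t1) return(NA_real_)
  abs(probe2 - probe1) * run$grid$dx / abs(t2 - t1)
}
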