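fr_xy <- fibre_frame(c(1, 0, 0), c(0, 1, 0))

test_that("reference conductivity has the diffusivities as eigenvalues", {
  cp <- conductivity_params()
  D <- conductivity_reference(cp, fr_xy)
  expect_equal(D, diag(c(cp$sigma_f, cp$sigma_s, cp$sigma_n)))
  expect_equal(sort(eigen(D)$values), sort(c(0.001, 0.0005, 0.00025)))
  set.seed(51)
  for (rep in 1:5) {
    fr <- random_frame()
    Dr <- conductivity_reference(cp, fr)
    expect_equal(sum(diag(Dr)), cp$sigma_f + cp$sigma_s + cp$sigma_n,
                 tolerance = 1e-14)
    expect_equal(sort(eigen(Dr, symmetric = TRUE)$values),
                 sort(c(cp$sigma_f, cp$sigma_s, cp$sigma_n)), tolerance = 1e-14)
  }
})

test_that("deformed conductivity reduces to the reference at identity", {
  cp <- conductivity_params()
  d0 <- deformation_state(diag(3))
  expect_equal(conductivity_deformed(cp, d0, fr_xy),
               conductivity_reference(cp, fr_xy), tolerance = 1e-14)
})

test_that("isochoric fibre extension divides the fibre coefficient by lambda^2", {
  cp <- conductivity_params()
  lam <- 1.17
  def <- isochoric_fibre_extension(lam, c(1, 0, 0))
  D <- conductivity_deformed(cp, def, fr_xy)
  expect_equal(D[1, 1], cp$sigma_f / lam^2, tolerance = 1e-12)
})

test_that("pull-back identities hold on random deformations", {
  set.seed(52)
  cp <- conductivity_params()
  for (rep in 1:15) {
    def <- random_deformation()
    fr <- random_frame()
    inv <- compute_invariants(def$C, fr)
    D0 <- conductivity_deformed(cp, def, fr, inv)
    # route 2: build the spatial tensor and pull it back explicitly
    F <- def$F
    Dsp <- cp$sigma_f * outer3(F %*% fr$f0) / inv$lam_f^2 +
      cp$sigma_s * outer3(F %*% fr$s0) / inv$lam_s^2 +
      cp$sigma_n * outer3(F %*% fr$n0) / inv$lam_n^2
    Fi <- solve(F)
    D0b <- def$J * Fi %*% Dsp %*% t(Fi)
    expect_lt(max(abs(D0 - D0b)) / max(abs(D0)), 1e-10)
    # effective-coefficient identities sigma* = J sigma / lam^2
    expect_equal(sum(fr$f0 * (D0 %*% fr$f0)), def$J * cp$sigma_f / inv$lam_f^2,
                 tolerance = 1e-10)
    expect_equal(sum(fr$s0 * (D0 %*% fr$s0)), def$J * cp$sigma_s / inv$lam_s^2,
                 tolerance = 1e-10)
    expect_equal(sum(fr$n0 * (D0 %*% fr$n0)), def$J * cp$sigma_n / inv$lam_n^2,
                 tolerance = 1e-10)
  }
})

test_that("stretch-activated current activates only under fibre stretch", {
  p <- list(g = 2, e_rev = -10)
  expect_equal(sac_current(40, 0.9, p), 0)
  expect_equal(sac_current(-10, 1.1, p), 0)   # reversal potential
  expect_equal(sac_current(0, 1.1, list(g = 0, e_rev = -10)), 0)
  expect_equal(sac_current(10, 1.1, p), 2 * 0.1 * 20)
  expect_equal(default_params()$sac$g, 0)     # inactive by default
})

test_that("stimulus protocols are windowed with the right integral", {
  stim <- apply_stimulus(0:2, duration = 2, amplitude = 3, t0 = 5)
  expect_equal(stim(0, 4.9), 0)
  expect_equal(stim(0, 7.0), 0)
  expect_equal(stim(1, 6.0), 3)
  expect_equal(stim(5, 6.0), 0)
  # integral over time per stimulated node = amplitude * duration
  dt <- 0.01
  tot <- sum(vapply(seq(0, 10, by = dt), function(t) stim(1, t), 0)) * dt
  expect_equal(tot, 3 * 2, tolerance = 1e-10)
  expect_error(apply_stimulus(integer(0)), "non-empty")
  # framework default stimulus duration is 2 ms
  expect_equal(formals(apply_stimulus)$duration, 2)
})

test_that("diffusion conserves and leaves constants unchanged", {
  grid <- em_grid(50, 0.01)
  # zero conductivity, no reaction, no stimulus: field unchanged
  V0 <- sin(seq_len(50))
  run0 <- run_monodomain(grid, matrix(0, 3, 3), dt = 0.1, n_steps = 20,
                         V0 = V0, reaction = NULL)
  expect_equal(run0$V[, ncol(run0$V)], V0, tolerance = 1e-12)
  # uniform field: discrete Laplacian of a constant is zero
  runc <- run_monodomain(grid, diag(c(1e-3, 0, 0)), dt = 0.1, n_steps = 20,
                         V0 = rep(0.7, 50), reaction = NULL)
  expect_equal(runc$V[, ncol(runc$V)], rep(0.7, 50), tolerance = 1e-12)
  # zero-flux boundaries conserve the total potential
  rund <- run_monodomain(grid, diag(c(1e-3, 0, 0)), dt = 0.1, n_steps = 200,
                         V0 = V0, reaction = NULL)
  expect_equal(sum(rund$V[, ncol(rund$V)]), sum(V0), tolerance = 1e-10)
})

test_that("a 3D box diffuses anisotropically along its axes", {
  grid <- em_grid(c(11, 11, 3), 0.05)
  V0 <- numeric(grid$n_nodes)
  centre <- 5 + 5 * 11 + 1 * 11 * 11 + 1   # middle node
  V0[centre] <- 1
  D <- diag(c(1e-3, 2.5e-4, 1e-4))
  run <- run_monodomain(grid, D, dt = 0.5, n_steps = 40, V0 = V0, reaction = NULL)
  Vend <- array(run$V[, ncol(run$V)], dim = grid$n)
  expect_equal(sum(Vend), 1, tolerance = 1e-10)     # conservation
  # faster spread along x than y
  expect_gt(Vend[9, 6, 2], Vend[6, 9, 2])
})

test_that("conduction velocity scales as the square root of the diffusivity", {
  cv_for <- function(sig) {
    grid <- em_grid(300, 0.01)
    run <- run_monodomain(grid, diag(c(sig, 0, 0)), dt = 0.02, n_steps = 7500,
                          stimulus = apply_stimulus(0:14, duration = 2, amplitude = 2),
                          record = 10L)
    conduction_velocity(run, 100, 250)
  }
  v1 <- cv_for(0.001)
  v2 <- cv_for(0.004)
  expect_false(is.na(v1) || is.na(v2))
  expect_equal(v2 / v1, 2, tolerance = 0.05)
})
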