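test_that("distortion-dependent unbinding rate follows its three branches", {
  expect_equal(gamma_su(0, 1), 0)            # gap branch
  expect_equal(gamma_su(-0.5, 5), 0)         # still the gap as printed
  expect_equal(gamma_su(-2, 1), 1)           # gamma*(-zeta-1)
  expect_equal(gamma_su(0.5, 2), 1)          # gamma*zeta
})

test_that("calcium sensitivity is length-dependent with a stretch cap", {
  p <- land_params()
  expect_equal(ca_t50(1, p), p$ca_t50_ref)
  expect_equal(ca_t50(1.5, p), ca_t50(1.2, p))
  p2 <- land_params(beta_1 = -1)
  expect_equal(ca_t50(0.9, p2), p2$ca_t50_ref + 0.1)
  expect_error(ca_t50(-1, p), "positive")
})

test_that("troponin equilibrium, distortion decay and fixed points are correct", {
  p <- land_params()
  # (Ca/CaT50)^n = 1  ->  CaTRPN* = 0.5
  q <- land_state(CaTRPN = 0.5)
  d <- land_rhs(q, ca_i = p$ca_t50_ref, lam_f = 1, dlam_f_dt = 0, p = p)
  expect_equal(d[["CaTRPN"]], 0, tolerance = 1e-12)
  # zeta relaxes to zero at zero stretch rate, rate c_s / c_w
  q2 <- unclass(land_state(zeta_s = 0.3, zeta_w = -0.2))
  d2 <- land_rhs(q2, 0.5, 1, 0, p)
  expect_equal(d2[["zeta_s"]], -p$c_s * 0.3)
  expect_equal(d2[["zeta_w"]], p$c_w * 0.2)
  # constant stretch rate v: steady zeta_s = A_s v / c_s
  v <- 0.01
  zs_star <- p$A_s * v / p$c_s
  d3 <- land_rhs(land_state(zeta_s = zs_star), 0.5, 1, v, p)
  expect_equal(d3[["zeta_s"]], 0, tolerance = 1e-12)
})

test_that("the occupancy rows respect the crossbridge flow topology", {
  p <- land_params()
  q <- unclass(land_state(S = 0.2, W = 0.3, CaTRPN = 0.5, B = 0.3))
  d <- land_rhs(q, 0.5, 1, 0, p)
  # flux leaving W through k_ws enters S: increasing k_ws by delta moves
  # exactly delta*W from the W row to the S row
  p2 <- p; p2$k_ws <- p$k_ws + 0.01
  d2 <- land_rhs(q, 0.5, 1, 0, p2)
  expect_equal(d2[["S"]] - d[["S"]], 0.01 * q[["W"]], tolerance = 1e-12)
  expect_equal(d2[["W"]] - d[["W"]], -0.01 * q[["W"]], tolerance = 1e-12)
  # B exchanges only with U: its flux does not touch S or W
  p3 <- p; p3$K_u <- p$K_u * 2
  d3 <- land_rhs(q, 0.5, 1, 0, p3)
  expect_equal(d3[["S"]], d[["S"]])
  expect_equal(d3[["W"]], d[["W"]])
})

test_that("integrated steady state matches the algebraic fixed point", {
  p <- land_params()
  for (ca in c(0.4, 0.805, 5)) {
    ss <- land_steady_state(ca, 1, p)
    tr <- integrate_land(land_state(), seq(0, 30000, 500),
                         ca_fn = function(t) ca, p = p,
                         rtol = 1e-10, atol = 1e-12)
    end <- unlist(tr[nrow(tr), c("S", "W", "CaTRPN", "B", "zeta_s", "zeta_w")])
    expect_equal(end, unclass(ss), tolerance = 1e-8, ignore_attr = TRUE)
    # and the fixed point really zeroes the right-hand side
    expect_lt(max(abs(land_rhs(ss, ca, 1, 0, p))), 1e-12)
  }
})

test_that("the length-dependence factor is continuous and saturates", {
  for (b0 in c(0.5, 2.3, 5)) {
    cut0 <- (1.87 * b0 - 1) / (2 * b0)
    for (edge in c(cut0, 0.87, 1.2)) {
      lo <- h_lambda(edge - 1e-9, b0)
      hi <- h_lambda(edge + 1e-9, b0)
      expect_equal(lo, hi, tolerance = 1e-6)
    }
    expect_equal(h_lambda(1, b0), 1)
    expect_equal(h_lambda(0.87, b0), 1 - 0.13 * b0, tolerance = 1e-12)
    expect_equal(h_lambda(1.2, b0), h_lambda(5, b0))
    expect_equal(h_lambda(1.2, b0), 1 + 0.2 * b0)
  }
  expect_error(h_lambda(1, -1), "positive")
})

test_that("active tension vanishes without crossbridges and scales with T_ref", {
  p <- land_params()
  expect_equal(active_tension(land_state(S = 0, W = 0), 1, p), 0)
  expect_equal(active_tension(land_state(S = 0.3, B = 0.6, zeta_s = -1, W = 0), 1, p), 0)
  q <- land_state(S = 0.1, W = 0.05, B = 0.8, zeta_s = 0.02, zeta_w = -0.01)
  p2 <- land_params(t_ref = 2 * p$t_ref)
  expect_equal(active_tension(q, 1.05, p2), 2 * active_tension(q, 1.05, p))
})

test_that("material active stress equals the explicit spatial pull-back", {
  set.seed(31)
  for (rep in 1:15) {
    def <- random_deformation()
    fr <- random_frame()
    inv <- compute_invariants(def$C, fr)
    ap <- active_stress_params(kort1 = 0.3, kort2 = 0.45, sigma0 = 800)
    Tact <- 5e4
    S1 <- active_pk2(Tact, def, fr, inv, ap)
    # spatial form of the active stress, then pull back J F^-1 sigma F^-T
    F <- def$F
    sig <- ((Tact + ap$sigma0) * outer3(F %*% fr$f0) / inv$lam_f^2 +
              ap$kort1 * Tact * outer3(F %*% fr$s0) / inv$lam_s^2 +
              ap$kort2 * Tact * outer3(F %*% fr$n0) / inv$lam_n^2) / def$J
    Fi <- solve(F)
    S2 <- def$J * Fi %*% sig %*% t(Fi)
    expect_lt(max(abs(S1 - S2)) / max(abs(S1)), 1e-10)
  }
})

test_that("active stress has the frame vectors as eigenvectors", {
  def <- random_deformation()
  fr <- fibre_frame(c(1, 1, 0), c(-1, 1, 1))
  inv <- compute_invariants(def$C, fr)
  S <- active_pk2(1e4, def, fr, inv, active_stress_params(0.2, 0.5, 100))
  for (v in list(fr$f0, fr$s0, fr$n0)) {
    Sv <- S %*% v
    expect_lt(max(abs(Sv - sum(Sv * v) * v)), 1e-9)
  }
  expect_equal(active_pk2(0, def, fr, inv, active_stress_params(0, 0, 0)),
               matrix(0, 3, 3))
  # rest state, fibre-only activation
  d0 <- deformation_state(diag(3))
  i0 <- compute_invariants(d0$C, fr)
  S0 <- active_pk2(300, d0, fr, i0, active_stress_params(0, 0, 50))
  expect_equal(S0, 350 * outer3(fr$f0), tolerance = 1e-12)
})
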