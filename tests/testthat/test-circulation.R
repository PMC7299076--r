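test_that("pre-stress penalty rule responds to volume drift", {
  p <- circulation_params()
  st <- circulation_state(phase = "initiation", v_endo = 159, sigma_0 = 5)
  expect_equal(prestress_update(st, 0, 1, p)$sigma_0, 5)
  expect_gt(prestress_update(st, 0.5, 1, p)$sigma_0, 5)
  expect_error(prestress_update(st, 0.5, -1, p), "dt")
  st2 <- circulation_state(phase = "ivc")
  expect_error(prestress_update(st2, 0, 1, p), "initiation")
  # closed-loop toy: a driver that holds V constant leaves sigma0 stationary
  sig <- numeric(20); s <- st
  for (k in 1:20) { s <- prestress_update(s, 0, 0.5, p); sig[k] <- s$sigma_0 }
  expect_equal(sig, rep(5, 20))
})

test_that("isovolumetric pressure rule counteracts volume drift linearly", {
  p <- circulation_params()
  st <- circulation_state(phase = "ivc", p_endo = 30)
  expect_equal(isovolumetric_pressure_update(st, 0, 1, p)$p_endo, 30)
  # contraction shrinking the cavity raises the pressure
  expect_gt(isovolumetric_pressure_update(st, -0.4, 1, p)$p_endo, 30)
  # halving Cp doubles the correction
  p2 <- circulation_params(inv_cp = 2 * p$inv_cp)
  d1 <- isovolumetric_pressure_update(st, -0.4, 1, p)$p_endo - 30
  d2 <- isovolumetric_pressure_update(st, -0.4, 1, p2)$p_endo - 30
  expect_equal(d2, 2 * d1)
  st_ivr <- circulation_state(phase = "ivr", p_endo = 40)
  expect_equal(isovolumetric_pressure_update(st_ivr, 0.2, 1, p)$p_endo,
               40 - p$inv_cp * 0.2)
  expect_error(isovolumetric_pressure_update(circulation_state("filling"), 0, 1, p),
               "ivc or ivr")
})

test_that("Windkessel step reproduces its closed forms", {
  p <- circulation_params()
  st <- circulation_state(phase = "ejection", p_art = 90)
  # zero flow: pure exponential decay, matched against the analytic solution
  s <- st
  t_tot <- 400; dt <- 2
  for (k in seq_len(t_tot / dt)) s <- windkessel_ejection_step(s, 0, dt, p)
  expect_equal(s$p_art, 90 * exp(-t_tot / (p$resistance * p$compliance)),
               tolerance = 1e-6)
  # constant outflow Q: P_art -> Q R
  Q <- 0.08
  s <- st
  for (k in 1:4000) s <- windkessel_ejection_step(s, -Q, 5, p)
  expect_equal(s$p_art, Q * p$resistance, tolerance = 1e-6)
  # R -> infinity: pure compliance, C dP = -dV
  pinf <- circulation_params(resistance = 1e12)
  s <- circulation_state(phase = "ejection", p_art = 50)
  s2 <- windkessel_ejection_step(s, -0.1, 1, pinf)
  expect_equal(s2$p_art - 50, 0.1 * 1 / pinf$compliance, tolerance = 1e-4)
})

test_that("the exact-exponential update is stable over the parameter ranges", {
  set.seed(61)
  tb <- sensitivity_param_table()
  cr <- tb[tb$name == "C", ]; rr <- tb[tb$name == "R", ]
  for (rep in 1:25) {
    C <- runif(1, cr$lower, cr$upper)
    R <- runif(1, rr$lower, rr$upper)
    p <- circulation_params(compliance = C, resistance = R)
    s <- circulation_state(phase = "ejection", p_art = 67.5)
    flows <- runif(200, -0.5, 0.05)
    for (f in flows) s <- windkessel_ejection_step(s, f, 5, p)
    expect_true(is.finite(s$p_art))
    expect_lt(abs(s$p_art), 0.5 * R + 70)   # bounded by the largest Q R
  }
})

test_that("filling decay is path independent", {
  p <- circulation_params()
  st <- circulation_state(phase = "filling", p_endo = 18, v_endo = 100)
  expect_equal(filling_step(st, 0, p)$p_endo, 18)
  expect_lt(filling_step(st, 2, p)$p_endo, 18)   # refilling lowers pressure
  # telescoping: many small increments equal one big one
  s <- st
  set.seed(62)
  dvs <- runif(50, 0, 1.2)
  for (dv in dvs) s <- filling_step(s, dv, p)
  expect_equal(s$p_endo, 18 - p$gamma * sum(dvs), tolerance = 1e-12)
})

test_that("phase transitions fire at the printed conditions", {
  p <- circulation_params()
  st <- circulation_state(phase = "ivc", p_endo = p$p_ej - 1)
  expect_equal(advance_phase(st, p)$phase, "ivc")
  st$p_endo <- p$p_ej + 0.5
  expect_equal(advance_phase(st, p)$phase, "ejection")
  # monotone-decreasing volume: no flow reversal, no ivr
  st2 <- circulation_state(phase = "ejection")
  expect_equal(advance_phase(st2, p, flow_history = c(-1, -0.5, -0.2))$phase,
               "ejection")
  # a constructed V(t) with a minimum triggers ivr within the window
  vt <- c(seq(150, 120, length.out = 20), seq(120.2, 130, length.out = 15))
  vdot <- diff(vt)
  fired <- NA
  st3 <- circulation_state(phase = "ejection")
  for (k in seq_along(vdot)) {
    st3 <- advance_phase(st3, p, flow_history = vdot[1:k])
    if (st3$phase == "ivr") { fired <- k; break }
  }
  expect_false(is.na(fired))
  expect_lte(abs(fired - 19), p$smoothing_window)
  # ivr -> filling below the threshold
  st4 <- circulation_state(phase = "ivr", p_endo = p$p_fill_threshold - 0.1)
  expect_equal(advance_phase(st4, p)$phase, "filling")
})

test_that("cavity volume integrates spheres and truncated ellipsoids", {
  m <- icosphere(4)
  expect_equal(euler_characteristic(m), 2)
  v <- cavity_volume(m)
  expect_lt(abs(v - 4 * pi / 3) / (4 * pi / 3), 0.005)
  # homogeneity: scaling coordinates by k scales the volume by k^3
  m2 <- m; m2$vertices <- 2.5 * m$vertices
  expect_equal(cavity_volume(m2), 2.5^3 * v, tolerance = 1e-10)
  # axis choice is immaterial for a closed surface
  expect_equal(cavity_volume(m, axis = c(0, 1, 0)), v, tolerance = 1e-12)
  # truncated ellipsoid against the closed-form cap volume
  a <- 2.5; b <- 2.2; cc <- 4.5; zb <- 1.8
  e <- truncated_ellipsoid(a, b, cc, zb, n_theta = 72, n_phi = 72)
  exact <- pi * a * b * (zb - zb^3 / (3 * cc^2) + 2 * cc / 3)
  expect_lt(abs(cavity_volume(e) - exact) / exact, 0.005)
  # displacement field shifts the integration onto the deformed surface
  u <- matrix(0, nrow(m$vertices), 3)
  expect_equal(cavity_volume(m, displacement = u), v)
  # an open surface is a geometry error
  holed <- m; holed$faces <- m$faces[-1, ]
  expect_error(cavity_volume(holed), "closed")
})

test_that("ASCII mesh formats round-trip", {
  m <- icosphere(1)
  for (ext in c("off", "obj", "stl")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_equal(cavity_volume(m2), cavity_volume(m), tolerance = 1e-8)
  }
  expect_error(read_mesh("mesh.xyz"), "unsupported")
})

test_that("circulation parameter invariants are enforced", {
  expect_error(circulation_params(p_ej = 10), "p_ej > p0")
  expect_error(circulation_params(compliance = -1), "positive")
  expect_error(circulation_params(bogus = 1), "unknown")
  expect_error(circulation_state(v_endo = -5), "positive")
})
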