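test_that("the OAT grid formula and row count are exact", {
  d <- oat_design(n_val = 10)
  expect_equal(nrow(d), 100)                       # 10 parameters x 10 levels
  # kort2 in [0, 0.6], level j = 4: A + 3 (B - A)/9 = 0.2
  expect_equal(d$kort2[d$.param == "kort2" & d$.level == 4], 0.2)
  tb <- sensitivity_param_table()
  for (nm in tb$name) {
    sweep <- d[d$.param == nm, ]
    expect_equal(sweep[[nm]][sweep$.level == 1], tb$lower[tb$name == nm])
    expect_equal(sweep[[nm]][sweep$.level == 10], tb$upper[tb$name == nm])
    # all other parameters sit at baseline
    others <- setdiff(tb$name, nm)
    for (o in others) expect_true(all(sweep[[o]] == tb$baseline[tb$name == o]))
  }
  expect_error(oat_design(n_val = 1), "at least 2")
})

test_that("LHS designs are stratified, bounded and seed-deterministic", {
  d <- lhs_design(seed = 7)
  expect_equal(nrow(d), 100)                       # 10 x number of parameters
  tb <- sensitivity_param_table()
  for (i in seq_len(nrow(tb))) {
    x <- d[[tb$name[i]]]
    expect_true(all(x >= tb$lower[i] & x <= tb$upper[i]))
    # exactly one point per equal-probability stratum
    u <- (x - tb$lower[i]) / (tb$upper[i] - tb$lower[i])
    occupancy <- table(findInterval(u, seq(0, 1, length.out = 101),
                                    rightmost.closed = TRUE))
    expect_true(all(occupancy == 1))
  }
  expect_identical(lhs_design(seed = 7), d)
  expect_false(identical(lhs_design(seed = 8), d))
  expect_error(lhs_design(), "seed")
})

test_that("the correlation coefficient matches hand and brute-force oracles", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlation_coefficient(x, 2 * x + 1), 1)
  expect_equal(correlation_coefficient(x, -x), -1)
  expect_equal(correlation_coefficient(x, c(1, 3, 2, 4)), 0.8)
  set.seed(81)
  for (rep in 1:10) {
    a <- rnorm(37); b <- rnorm(37)
    # from-scratch double-loop evaluation of the printed formula
    am <- 0; bm <- 0
    for (i in seq_along(a)) { am <- am + a[i] / 37; bm <- bm + b[i] / 37 }
    num <- 0; da <- 0; db <- 0
    for (i in seq_along(a)) {
      num <- num + (a[i] - am) * (b[i] - bm)
      da <- da + (a[i] - am)^2
      db <- db + (b[i] - bm)^2
    }
    expect_equal(correlation_coefficient(a, b), num / sqrt(da * db),
                 tolerance = 1e-12)
    expect_equal(correlation_coefficient(a, b), stats::cor(a, b),
                 tolerance = 1e-12)
  }
  expect_error(correlation_coefficient(x, rep(1, 4)), "zero variance")
  expect_error(correlation_coefficient(1:2, 1:2), "at least 3")
})

test_that("partial correlation adjusts away confounding", {
  set.seed(82)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 2 * X[, "x1"] + rnorm(n, sd = 0.3)
  expect_lt(abs(partial_correlation(X, y, "x2")), 0.1)      # simulated null
  # independent columns: PCC close to CC for a linear response
  expect_equal(partial_correlation(X, y, "x1"),
               correlation_coefficient(X[, "x1"], y), tolerance = 0.05)
  # confounded raw correlation, recovered direct effect
  x1 <- rnorm(n)
  x2 <- -0.9 * x1 + rnorm(n, sd = 0.2)    # strong negative confounder
  yy <- x1 + x2 + rnorm(n, sd = 0.1)
  Xc <- cbind(x1 = x1, x2 = x2)
  expect_gt(partial_correlation(Xc, yy, "x1"), 0.5)
  # rank-deficient adjustment set is reported
  Xd <- cbind(a = x1, b = x1, y2 = rnorm(n))
  expect_error(partial_correlation(Xd, yy, "y2"), "rank-deficient")
})

test_that("PRCC linearises monotone maps and controls false positives", {
  set.seed(83)
  n <- 100
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  y <- X[, "a"]^3 + rnorm(n, sd = 1e-3)
  pr <- prcc(X, y, "a")
  expect_gt(pr$prcc, 0.99)
  expect_lt(pr$p_value, 1e-10)
  # invariance under strictly monotone transforms of y
  pr2 <- prcc(X, exp(3 * y), "a")
  expect_equal(pr2$prcc, pr$prcc, tolerance = 1e-12)
  # null: p <= 0.05 in at most ~5% of repeats (allow 10%)
  fp <- 0
  for (rep in 1:100) {
    yn <- rnorm(n)
    if (prcc(X, yn, "a")$p_value <= 0.05) fp <- fp + 1
  }
  expect_lte(fp, 10)
  # PRCC with a single parameter equals the plain rank correlation
  x1 <- matrix(runif(50), ncol = 1, dimnames = list(NULL, "x"))
  yy <- runif(50)
  expect_equal(prcc(x1, yy, 1)$prcc,
               stats::cor(rank(x1[, 1]), rank(yy)), tolerance = 1e-12)
  expect_true(abs(prcc(X, y, "a")$prcc) <= 1)
})

test_that("the sensitivity report marks signs, masks failures and is equivariant", {
  set.seed(84)
  n <- 80
  design <- tibble::tibble(T_ref = runif(n, 60, 1200), C = runif(n, 0.1, 0.4),
                           R = runif(n, 75, 750))
  bio <- tibble::tibble(
    EF = 30 + 0.02 * design$T_ref + rnorm(n, sd = 2),
    WT = rnorm(n)
  )
  rep1 <- sensitivity_report(design, bio)
  cell <- rep1[rep1$parameter == "T_ref" & rep1$biomarker == "EF", ]
  expect_true(cell$significant)
  expect_equal(cell$sign, "+")
  expect_s3_class(autoplot(rep1), "ggplot")
  expect_equal(glance(rep1)$n_failed, 0)
  # permutation equivariance of the parameter columns
  rep2 <- sensitivity_report(design[, c(3, 1, 2)], bio)
  j1 <- dplyr::arrange(tidy(rep1), parameter, biomarker)
  j2 <- dplyr::arrange(tidy(rep2), parameter, biomarker)
  expect_equal(j1$prcc, j2$prcc, tolerance = 1e-12)
  # failed rows are excluded pairwise, too many failures refuse
  bio_some_na <- bio; bio_some_na$EF[1:5] <- NA
  rep3 <- sensitivity_report(design, bio_some_na)
  expect_equal(attr(rep3, "n_failed"), 5)
  bio_bad <- bio; bio_bad$EF[1:40] <- NA
  expect_error(sensitivity_report(design, bio_bad), "refusing")
  # all-noise responses: rarely any significant entry
  hits <- 0
  for (r in 1:40) {
    noise <- tibble::tibble(EF = rnorm(n))
    rp <- sensitivity_report(design, noise)
    if (any(rp$significant)) hits <- hits + 1
  }
  expect_lte(hits / 40, 0.35)   # 3 tests at alpha 0.05 -> ~14% expected
})

test_that("OAT monotonicity screening counts sign changes", {
  d <- oat_design(n_val = 6)
  # response monotone in every parameter
  resp <- rowSums(scale(dplyr::select(d, -".param", -".level")))
  mono <- oat_monotonicity(d, resp)
  expect_true(all(mono$monotone))
  # inject a non-monotone response for one parameter
  resp2 <- resp
  idx <- which(d$.param == "kort2")
  resp2[idx] <- c(0, 1, 0, 1, 0, 1)
  mono2 <- oat_monotonicity(d, resp2)
  expect_false(mono2$monotone[mono2$parameter == "kort2"])
  expect_gt(mono2$sign_changes[mono2$parameter == "kort2"], 2)
})
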