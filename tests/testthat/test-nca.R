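profile_of <- function(t, c_, tissue = "blood", route = "IV", g = "") {
  concentration_profile(t, c_, tissue, route, g)
}

test_that("trapezoidal AUC is exact on simple shapes", {
  expect_equal(auc_trapezoid(profile_of(c(0, 100), c(7, 7))), 700)
  expect_equal(auc_trapezoid(profile_of(c(0, 60), c(0, 600))), 18000)
  p <- profile_of(c(0, 15, 120, 480), c(0, 4600, 466, 0))
  expect_equal(auc_trapezoid(p), 34500 + 265965 + 83880)
})

test_that("AUC is additive over adjacent intervals and interpolates t_end", {
  p <- profile_of(c(0, 15, 120, 480), c(0, 4600, 466, 0))
  expect_equal(auc_trapezoid(p, 120) +
                 (auc_trapezoid(p, 480) - auc_trapezoid(p, 120)),
               auc_trapezoid(p, 480))
  # t_end inside a segment: piecewise-linear exactness
  expect_equal(auc_trapezoid(p, 60),
               34500 + (4600 + 4600 - (4600 - 466) * 45 / 105) / 2 * 45)
  # additivity at an interior cut point
  expect_equal(auc_trapezoid(p, 60) + (auc_trapezoid(p) - auc_trapezoid(p, 60)),
               auc_trapezoid(p))
})

test_that("AUC never extrapolates beyond the last observation", {
  p <- profile_of(c(0, 60, 120), c(10, 8, 6))
  expect_equal(auc_trapezoid(p, 480), auc_trapezoid(p, 120))
  expect_error(auc_trapezoid(profile_of(30, 5)), "at least 2")
  expect_error(auc_trapezoid(p, -10), "precedes")
})

test_that("terminal Ke is exact for noiseless exponentials", {
  for (grid in list(c(10, 30, 60, 120, 240, 480), c(5, 50, 400),
                    c(100, 200, 300, 444))) {
    p <- profile_of(grid, 100 * exp(-0.017 * grid))
    expect_equal(terminal_ke(p)$ke, 0.017, tolerance = 1e-12)
  }
  expect_equal(terminal_ke(profile_of(1:5, 10 * exp(-0.005 * (1:5))),
                           n_points = 5)$t_half,
               log(2) / 0.005, tolerance = 1e-9)
})

test_that("terminal Ke rejects flat, rising or censored windows", {
  expect_error(terminal_ke(profile_of(1:4, rep(3, 4))), "non-negative")
  expect_error(terminal_ke(profile_of(1:4, c(1, 2, 3, 4))), "non-negative")
  expect_error(terminal_ke(profile_of(1:4, c(5, 4, 1, 0))), "non-positive")
  expect_error(terminal_ke(profile_of(1:2, c(2, 1))), "fewer than 3")
})

test_that("Cmax/Tmax pick the earliest maximum", {
  iv <- profile_of(c(15, 30, 60, 120), c(4600, 3000, 1500, 466))
  expect_equal(cmax_tmax(iv), list(cmax = 4600, tmax = 15))
  plateau <- profile_of(1:5, c(1, 7, 7, 7, 2))
  expect_equal(cmax_tmax(plateau)$tmax, 2)
  single <- profile_of(45, 1000)
  expect_equal(cmax_tmax(single), list(cmax = 1000, tmax = 45))
})

test_that("brain/blood ratio requires shared observations by default", {
  t <- c(15, 30, 60)
  brain <- profile_of(t, c(300, 780, 500), tissue = "brain")
  blood <- profile_of(t, c(4600, 3000, 1500))
  expect_equal(brain_blood_ratio(brain, blood, 30), 780 / 3000)
  same <- brain_blood_ratio(brain, brain, 15)
  expect_equal(same, 1)
  expect_error(brain_blood_ratio(brain, blood, 45), "no observation")
  zero <- profile_of(t, c(1, 0, 1))
  expect_error(brain_blood_ratio(brain, zero, 30), "zero")
})

test_that("log-linear interpolation recovers exponential profiles exactly", {
  t <- c(10, 60, 240)
  brain <- profile_of(t, 50 * exp(-0.01 * t), tissue = "brain")
  blood <- profile_of(t, 200 * exp(-0.01 * t))
  expect_equal(brain_blood_ratio(brain, blood, 100, interpolate = TRUE),
               0.25, tolerance = 1e-12)
})

test_that("DTE and DTP reproduce the study's targeting panel", {
  a <- reference_aucs()
  expect_equal(round(dte(a$brain_in, a$blood_in, a$brain_iv, a$blood_iv), 1),
               509.2)
  expect_equal(round(dtp(a$brain_in, a$blood_in, a$brain_iv, a$blood_iv), 1),
               80.4)
  # intranasal solution group against the same intravenous reference
  expect_equal(round(dte(a$sol_brain_in, a$sol_blood_in,
                         a$brain_iv, a$blood_iv), 1), 412.6)
  # printed AUC quotients
  expect_equal(round(a$brain_in / a$blood_in, 2), 1.22)
  expect_equal(round(a$sol_brain_in / a$sol_blood_in, 2), 0.99)
  expect_equal(round(a$brain_iv / a$blood_iv, 2), 0.24)
})

test_that("DTP and DTE obey their algebraic identity and edge cases", {
  a <- reference_aucs()
  D <- dte(a$brain_in, a$blood_in, a$brain_iv, a$blood_iv)
  P <- dtp(a$brain_in, a$blood_in, a$brain_iv, a$blood_iv)
  expect_equal(P, 100 * (1 - 100 / D), tolerance = 1e-12)

  expect_equal(dte(10, 20, 30, 60), 100)
  # brain exposure exactly explained by systemic redistribution
  expect_equal(dtp(50, 100, 25, 50), 0)
  expect_error(dte(0, 1, 1, 1), "positive")
  expect_error(dtp(-1, 1, 1, 1), "positive")
})

test_that("targeting metrics are invariant to a common concentration scale", {
  sim <- simulate_pk_study(pk_sim_params())
  scaled <- lapply(sim$profiles, function(p) {
    concentration_profile(p$time, 3.7 * p$concentration, p$tissue, p$route)
  })
  tm1 <- targeting_metrics(sim$profiles$brain_in, sim$profiles$blood_in,
                           sim$profiles$brain_iv, sim$profiles$blood_iv)
  tm2 <- targeting_metrics(scaled$brain_in, scaled$blood_in,
                           scaled$brain_iv, scaled$blood_iv)
  expect_equal(tm2$dte, tm1$dte)
  expect_equal(tm2$dtp, tm1$dtp)
  expect_equal(tm2$conc_ratio_in, tm1$conc_ratio_in)
  expect_equal(tm2$auc_ratio_in, tm1$auc_ratio_in)
})

test_that("targeting metrics check profile roles", {
  sim <- simulate_pk_study(pk_sim_params())
  expect_error(
    targeting_metrics(sim$profiles$blood_in, sim$profiles$brain_in,
                      sim$profiles$brain_iv, sim$profiles$blood_iv),
    "should be brain/IN")
})

test_that("profiles validate ordering and signs", {
  expect_error(concentration_profile(c(1, 1, 2), c(1, 2, 3), "blood", "IV"),
               "duplicate")
  expect_error(concentration_profile(c(2, 1), c(1, 2), "blood", "IV"),
               "increasing")
  expect_error(concentration_profile(c(-1, 1), c(1, 2), "blood", "IV"),
               "non-negative")
  expect_error(concentration_profile(1, -2, "blood", "IV"), "non-negative")
})
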