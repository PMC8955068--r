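test_that("noiseless surface simulation round-trips through the fitter", {
  beta <- c(`(Intercept)` = 12.7979, x1 = 1.87247, x2 = -0.580015,
            x3 = -0.140025)
  ts <- true_surface("sqrt", beta, noise_sd = 0)
  sim <- simulate_bbd_study(berberine_factors(), 5, list(PS = ts), seed = 4)
  expect_equal(nrow(sim$runs), 17)
  fit <- fit_rsm(sim$design, sim$runs$PS, "linear", "sqrt")
  expect_equal(coef(fit), beta, tolerance = 1e-12)
})

test_that("surface simulation is reproducible and noise-calibrated", {
  beta <- c(`(Intercept)` = 12.8, x1 = 1.9, x2 = -0.6, x3 = -0.14)
  ts <- true_surface("sqrt", beta, noise_sd = 0.157)
  a <- simulate_bbd_study(berberine_factors(), 5, list(PS = ts), seed = 99)
  b <- simulate_bbd_study(berberine_factors(), 5, list(PS = ts), seed = 99)
  expect_identical(a$runs, b$runs)

  # intercept sampling error over replicates matches OLS theory:
  # SE(intercept) = sd / sqrt(n), so mean |error| = SE * sqrt(2/pi)
  errs <- vapply(1:200, function(s) {
    sim <- simulate_bbd_study(berberine_factors(), 5, list(PS = ts), seed = s)
    unname(coef(fit_rsm(sim$design, sim$runs$PS, "linear", "sqrt"))[1]) - 12.8
  }, numeric(1))
  theory <- 0.157 / sqrt(17) * sqrt(2 / pi)
  expect_equal(mean(abs(errs)), theory, tolerance = 0.2)
})

test_that("the PK simulator's truth has no targeting without direct input", {
  sim <- simulate_pk_study(pk_sim_params(f_direct = 0))
  expect_equal(sim$truth$dte, 100, tolerance = 1e-9)
  expect_equal(sim$truth$dtp, 0, tolerance = 1e-12)

  # and the trapezoid estimator agrees on a dense, long grid
  dense <- simulate_pk_study(
    pk_sim_params(f_direct = 0, times = c(0, seq(2, 4000, by = 2))))
  a <- vapply(dense$profiles, auc_trapezoid, numeric(1))
  expect_equal(dte(a[["brain_in"]], a[["blood_in"]],
                   a[["brain_iv"]], a[["blood_iv"]]),
               100, tolerance = 1e-3)
})

test_that("direct transport rises monotonically with the direct fraction", {
  fds <- c(0, 0.2, 0.5, 0.8)
  dtps <- vapply(fds, function(fd) {
    simulate_pk_study(pk_sim_params(f_direct = fd))$truth$dtp
  }, numeric(1))
  expect_true(all(diff(dtps) > 0))

  # estimator view on a dense grid preserves the ordering
  est <- vapply(c(0.2, 0.5), function(fd) {
    s <- simulate_pk_study(
      pk_sim_params(f_direct = fd, times = c(0, seq(5, 2000, by = 5))))
    a <- vapply(s$profiles, auc_trapezoid, numeric(1))
    dtp(a[["brain_in"]], a[["blood_in"]], a[["brain_iv"]], a[["blood_iv"]])
  }, numeric(1))
  expect_lt(est[1], est[2])
})

test_that("noiseless profiles return the generating rate constants", {
  p <- pk_sim_params()
  sim <- simulate_pk_study(p)
  # IV blood is mono-exponential: terminal fit is exact
  expect_equal(terminal_ke(sim$profiles$blood_iv)$ke, p$k, tolerance = 1e-12)
  # same seed, same draw
  noisy1 <- simulate_pk_study(pk_sim_params(noise_cv = 0.2, seed = 11))
  noisy2 <- simulate_pk_study(pk_sim_params(noise_cv = 0.2, seed = 11))
  expect_identical(noisy1$profiles$brain_in$concentration,
                   noisy2$profiles$brain_in$concentration)
})

test_that("brain mass balance closes against numerical integration", {
  p <- pk_sim_params(f_direct = 0.4)
  curves <- nose2brain:::pk_curves(p)
  # total brain input = kin * AUC_blood(IN) + direct depot delivery;
  # efflux removes kout * AUC_brain(IN); both integrals taken to infinity
  auc_blood <- stats::integrate(curves$blood_in, 0, Inf,
                                rel.tol = 1e-10)$value
  auc_brain <- stats::integrate(curves$brain_in, 0, Inf,
                                rel.tol = 1e-10)$value
  direct_in <- 1000 * p$f_direct * p$dose_ug / p$v_brain_ml
  expect_equal(p$kin * auc_blood + direct_in, p$kout * auc_brain,
               tolerance = 1e-6)
  # closed-form truth AUCs match quadrature
  truth <- nose2brain:::pk_true_auc(p)
  expect_equal(truth$blood_in, auc_blood, tolerance = 1e-8)
  expect_equal(truth$brain_in, auc_brain, tolerance = 1e-8)
})

test_that("simulated permeation runs invert the sampling bookkeeping", {
  run <- simulate_permeation(10.63, times_h = 1:12)
  expect_equal(steady_state_flux(run$times_h, cumulative_per_area(run)),
               10.63, tolerance = 1e-9)

  lagged <- simulate_permeation(8, lag_h = 2, times_h = 1:12)
  q <- cumulative_per_area(lagged)
  expect_equal(q[1:2], c(0, 0))
  expect_equal(steady_state_flux(lagged$times_h, q, window = 3:12), 8,
               tolerance = 1e-9)

  none <- simulate_permeation(0, times_h = 1:6)
  expect_equal(cumulative_per_area(none), rep(0, 6))
})

test_that("noisy permeation recovers the flux within sampling error", {
  est <- vapply(1:100, function(s) {
    run <- simulate_permeation(10.63, times_h = 1:12, noise_cv = 0.05,
                               seed = s)
    steady_state_flux(run$times_h, cumulative_per_area(run))
  }, numeric(1))
  se <- stats::sd(est)
  expect_lt(abs(mean(est) - 10.63), 3 * se / sqrt(100) + 0.05)
})

test_that("simulator parameter validation catches degenerate inputs", {
  expect_error(pk_sim_params(k = 0.01, kout = 0.01), "pairwise distinct")
  expect_error(pk_sim_params(f_direct = 1.2))
  ts <- true_surface("sqrt", c(`(Intercept)` = 1), noise_sd = 0)
  expect_error(true_surface("sqrt", c(x1 = 1)), "Intercept")
  # a surface living near the sqrt domain boundary triggers redraws
  low <- true_surface("sqrt", c(`(Intercept)` = 0.05), noise_sd = 0.2)
  expect_warning(
    simulate_bbd_study(berberine_factors(), 5, list(Y = low), seed = 2),
    "redrew")
})
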