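# ---- fitting ------------------------------------------------------------

test_that("linear fits agree with the Box-Behnken contrast oracle", {
  des <- bb_design()
  set.seed(7)
  for (i in 1:5) {
    y <- rnorm(17, mean = 100, sd = 10)
    fit <- fit_rsm(des, y, "linear", "identity")
    expect_equal(coef(fit), bbd_linear_oracle(des$coded, y),
                 tolerance = 1e-9)
  }
  # and on a transformed scale
  runs <- bb_runs()
  fit <- fit_rsm(des, runs$PS, "linear", "sqrt")
  expect_equal(coef(fit), bbd_linear_oracle(des$coded, sqrt(runs$PS)),
               tolerance = 1e-9)
})

test_that("particle-size and release models reproduce the study equations", {
  runs <- bb_runs()
  des <- bb_design(runs)

  ps <- fit_rsm(des, runs$PS, "linear", "sqrt", response_name = "PS")
  expect_equal(unname(coef(ps)),
               c(12.7979, 1.87247, -0.580015, -0.140025), tolerance = 1e-5)

  cdr <- fit_rsm(des, runs$CDR, "linear", "identity", response_name = "CDR")
  expect_equal(unname(coef(cdr)), c(71.2471, -1.025, 4.7125, 13.0875),
               tolerance = 1e-5)
})

test_that("noiseless synthetic responses are recovered to machine precision", {
  des <- bbd_design(berberine_factors(), 5)
  beta <- c(`(Intercept)` = 50, x1 = 3, x2 = -2, x3 = 0.5,
            `x1:x3` = 1.2, `x1^2` = -0.8, `x2^2` = 0.3, `x3^2` = 0.1)
  terms <- setdiff(names(beta), "(Intercept)")
  y <- drop(nose2brain:::term_matrix(des$coded, terms) %*% beta)
  fit <- fit_rsm(des, y, terms, "identity")
  expect_equal(coef(fit), beta, tolerance = 1e-12)
  st <- fit_stats(fit)
  expect_equal(st$r_squared, 1, tolerance = 1e-12)
  expect_equal(st$adj_r_squared, 1, tolerance = 1e-12)
})

test_that("degenerate designs raise clear fitting errors", {
  # a slice holding GMS constant makes its coded column identically zero
  runs <- bb_runs()
  slice <- runs[runs$GMS == 150, ]
  des <- as_bbd_design(slice, berberine_factors())
  expect_error(fit_rsm(des, slice$PS, "linear", "sqrt"), "singular")
  # more terms than runs is rejected before factorization
  few <- as_bbd_design(runs[1:8, ], berberine_factors())
  expect_error(fit_rsm(few, runs$PS[1:8], "quadratic", "sqrt"),
               "too few runs")
})

# ---- ANOVA --------------------------------------------------------------

test_that("Type III ANOVA reproduces the study's F statistics", {
  runs <- bb_runs()
  des <- bb_design(runs)
  an <- anova_type3(fit_rsm(des, runs$PS, "linear", "sqrt"))

  expect_equal(an$model$statistic, 416.50, tolerance = 1e-4)
  expect_lt(an$model$p_value, 1e-4)
  expect_equal(an$terms$statistic, c(1134.32, 108.84, 6.34), tolerance = 1e-4)
  expect_equal(an$lack_of_fit$statistic, 0.3386, tolerance = 1e-4)
  expect_equal(an$lack_of_fit$p_value, 0.9183, tolerance = 1e-4)
  expect_equal(an$lack_of_fit$df_lof, 9L)
  expect_equal(an$lack_of_fit$df_pe, 4L)
})

test_that("ANOVA sums of squares decompose additively", {
  runs <- bb_runs()
  des <- bb_design(runs)
  for (resp in c("PS", "EE", "CDR")) {
    tr <- berberine_config()$responses[[resp]]$transform
    an <- anova_type3(fit_rsm(des, runs[[resp]], "linear", tr))
    expect_equal(an$ss$total, an$ss$regression + an$ss$residual)
    expect_equal(an$ss$residual,
                 an$lack_of_fit$ss_lof + an$lack_of_fit$ss_pe)
  }
})

test_that("zeta potential shows no significant factor effects", {
  runs <- bb_runs()
  des <- bb_design(runs)
  an <- anova_type3(fit_rsm(des, runs$ZP, "linear", "identity"))
  expect_true(all(an$terms$p_value > 0.05))
})

test_that("partial and sequential SS coincide on the orthogonal linear block", {
  runs <- bb_runs()
  des <- bb_design(runs)
  y <- sqrt(runs$PS)
  an <- anova_type3(fit_rsm(des, runs$PS, "linear", "sqrt"))
  # sequential SS for an orthogonal column: (contrast)^2 / 8
  seq_ss <- vapply(1:3, function(j) {
    (sum(y[des$coded[, j] == 1]) - sum(y[des$coded[, j] == -1]))^2 / 8
  }, numeric(1))
  expect_equal(an$terms$ss, seq_ss, tolerance = 1e-9)
})

test_that("a noiseless linear response yields a vanishing residual", {
  des <- bbd_design(berberine_factors(), 5)
  y <- 10 + 2 * des$coded[, 1] - des$coded[, 3]
  an <- anova_type3(fit_rsm(des, y, "linear", "identity"))
  expect_lt(an$ss$residual, 1e-20)
  expect_lt(an$model$p_value, 1e-12)
})

test_that("lack of fit is reported unavailable without replicates", {
  des <- bbd_design(berberine_factors(), 1)
  set.seed(3)
  an <- anova_type3(fit_rsm(des, rnorm(13, 100), "linear", "identity"))
  expect_false(an$lack_of_fit$available)
  expect_true(is.na(an$lack_of_fit$statistic))
})

# ---- fit statistics -----------------------------------------------------

test_that("diagnostic panel matches the study's reported values", {
  runs <- bb_runs()
  des <- bb_design(runs)

  ps <- fit_stats(fit_rsm(des, runs$PS, "linear", "sqrt"))
  expect_equal(ps$r_squared, 0.9897, tolerance = 1e-4)
  expect_equal(ps$sd, 0.1573, tolerance = 1e-3)
  expect_equal(ps$cv_percent, 1.23, tolerance = 1e-2)
  expect_equal(ps$adequate_precision, 64.3041, tolerance = 1e-4)
  expect_equal(ps$pred_r_squared, 0.9845, tolerance = 1e-4)
  expect_equal(ps$adj_r_squared, 0.9873, tolerance = 1e-4)

  cdr <- fit_stats(fit_rsm(des, runs$CDR, "linear", "identity"))
  expect_equal(cdr$r_squared, 0.9915, tolerance = 1e-4)
  expect_equal(cdr$adequate_precision, 72.4640, tolerance = 1e-4)
})

test_that("predicted R2 <= adjusted R2 <= R2 on all study fits", {
  for (fit in bb_fits()) {
    st <- fit_stats(fit)
    expect_lte(st$pred_r_squared, st$adj_r_squared + 1e-12)
    expect_lte(st$adj_r_squared, st$r_squared + 1e-12)
    expect_lte(st$r_squared, 1)
  }
})

test_that("a constant response gives an undefined-statistic error", {
  des <- bbd_design(berberine_factors(), 2)
  fit <- fit_rsm(des, rep(5, 14), "linear", "identity")
  expect_error(fit_stats(fit), "undefined")
})

# ---- model reduction ----------------------------------------------------

test_that("entrapment model reduces to the study's retained quadratic", {
  runs <- bb_runs()
  des <- bb_design(runs)
  full <- fit_rsm(des, runs$EE, "quadratic", "inverse", response_name = "EE")
  red <- reduce_model(full, alpha = 0.05)
  expect_equal(red$terms,
               c("x1", "x2", "x3", "x1:x3", "x1^2", "x2^2", "x3^2"))
  expect_equal(signif(unname(coef(red))[2], 2), -0.0024)
  expect_equal(unname(coef(red)),
               c(0.0121807, -0.0024, 0.0003, -0.0014, 0.0012, 0.0009,
                 0.0008, 0.0005),
               tolerance = 5e-2)
})

test_that("reduction leaves significant or protected models unchanged", {
  runs <- bb_runs()
  des <- bb_design(runs)
  lin <- fit_rsm(des, runs$PS, "linear", "sqrt")
  expect_equal(reduce_model(lin, 0.05)$terms, lin$terms)

  full <- fit_rsm(des, runs$EE, "quadratic", "inverse")
  expect_equal(reduce_model(full, alpha = 1)$terms, full$terms)
})

test_that("weak heredity is preserved during reduction", {
  des <- bbd_design(berberine_factors(), 5)
  set.seed(11)
  # pure-noise response: reduction should never strand a child term
  y <- rnorm(17, 100, 5)
  red <- reduce_model(fit_rsm(des, y, "quadratic", "identity"), 0.05)
  hierarchy_ok <- vapply(red$terms, function(t) {
    all(nose2brain:::term_parents(t) %in% red$terms)
  }, logical(1))
  expect_true(all(hierarchy_ok))
  expect_true(all(red$terms %in% rsm_terms("quadratic")))
})

# ---- prediction ---------------------------------------------------------

test_that("predictions back-transform and match the study's optimum", {
  fits <- bb_fits()
  pt <- c(-0.706, 0.6, 1)
  expect_equal(predict(fits$PS, pt), 119.8, tolerance = 0.01)
  expect_equal(predict(fits$EE, pt), 76.1, tolerance = 0.01)
  expect_equal(predict(fits$CDR, pt), 88.2, tolerance = 0.005)
})

test_that("prediction at the centre returns the back-transformed intercept", {
  for (fit in bb_fits()) {
    expect_equal(predict(fit, c(0, 0, 0)),
                 inverse_transform(unname(coef(fit)[1]), fit$transform))
  }
})

test_that("predicting at design points reproduces stored fitted values", {
  for (fit in bb_fits()) {
    expect_equal(predict(fit),
                 inverse_transform(fit$fitted, fit$transform),
                 tolerance = 1e-12)
  }
})

test_that("prediction guards the coded cube and the transform domain", {
  fits <- bb_fits()
  expect_error(predict(fits$PS, c(2, 0, 0)), "extrapolate")
  expect_silent(predict(fits$PS, c(1.19, 0, 0)))
  # far extrapolation of the sqrt model drives its linear predictor
  # negative, which cannot be squared back onto the size scale
  expect_error(predict(fits$PS, c(-8, 0, 0), extrapolate = TRUE),
               "non-positive")
})
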