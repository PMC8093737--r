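test_that("noiseless power-law data is recovered exactly", {
  fit <- exact_fit(a = 2, b = 2.5)
  expect_equal(fit$intercept, log(2), tolerance = 1e-10)
  expect_equal(fit$slope, 2.5, tolerance = 1e-10)
  expect_equal(fit$residual_scale, 0, tolerance = 1e-8)
  expect_equal(fit$df, 1L)
})

test_that("the four-point fit matches hand-solved OLS values", {
  fit <- four_point_fit()
  expect_equal(fit$slope, 2.52, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.97, tolerance = 1e-10)
  expect_equal(fit$residual_scale, sqrt(0.018 / 2), tolerance = 1e-10)
  expect_equal(fit$mean_logx, 1.5)
  expect_equal(fit$sxx, 5)

  p <- predict_log(fit, exp(1.5))
  expect_equal(p$mu_log, 4.75, tolerance = 1e-10)
  expect_equal(p$se_fit, fit$residual_scale / 2, tolerance = 1e-10)
  expect_equal(p$se_pred, sqrt(0.01125), tolerance = 1e-10)

  pi_ <- prediction_interval(fit, exp(1.5))
  half <- qt(0.975, 2) * sqrt(0.01125)
  expect_equal(pi_$point_kg, exp(4.75), tolerance = 1e-10)
  expect_equal(pi_$lwr_kg, exp(4.75 - half), tolerance = 1e-10)
  expect_equal(pi_$upr_kg, exp(4.75 + half), tolerance = 1e-10)
  # sanity against the rounded hand computation
  expect_equal(round(pi_$point_kg, 1), 115.6)
  expect_equal(round(pi_$lwr_kg, 1), 73.2)
})

test_that("invalid calibration inputs are rejected", {
  expect_error(fit_loglog(tibble::tibble(diameter_cm = c(1, 2), mass_kg = c(1, 2))),
               "At least 3")
  expect_error(fit_loglog(tibble::tibble(diameter_cm = c(1, 2, -1), mass_kg = c(1, 2, 3))),
               "positive")
  expect_error(fit_loglog(tibble::tibble(diameter_cm = c(2, 2, 2), mass_kg = c(1, 2, 3))),
               "distinct")
  expect_error(predict_log(four_point_fit(), -1), "positive")
})

test_that("fit_loglog agrees with the normal-equations oracle", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- runif(n, 0.5, 30)
    m <- 0.1 * d^2.4 * exp(rnorm(n, 0, 0.4))
    fit <- fit_loglog(tibble::tibble(diameter_cm = d, mass_kg = m))
    ora <- ols_oracle(log(d), log(m))
    expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
    expect_equal(fit$residual_scale, ora$residual_scale, tolerance = 1e-10)
    expect_equal(fit$slope_se, ora$slope_se, tolerance = 1e-10)
  }
})

test_that("prediction standard errors and back-transform behave as derived", {
  fit <- four_point_fit()
  d <- exp(seq(log(0.1), log(100), length.out = 50))
  p <- predict_log(fit, d)
  # quadrature sum dominates both parts
  expect_true(all(p$se_pred >= p$se_fit))
  expect_true(all(p$se_pred >= fit$residual_scale - 1e-12))
  # exp(mu) is exactly the power function a * D^b
  expect_equal(exp(p$mu_log), exp(fit$intercept) * d^fit$slope, tolerance = 1e-12)
  # multiplicative symmetry of the back-transformed interval
  pi_ <- prediction_interval(fit, d)
  expect_equal(pi_$lwr_kg * pi_$upr_kg, pi_$point_kg^2, tolerance = 1e-10)
  expect_true(all(pi_$lwr_kg <= pi_$point_kg & pi_$point_kg <= pi_$upr_kg))
})

test_that("prediction bands have the right grid and monotone widths", {
  fit <- four_point_fit()
  band <- prediction_band(fit, 2.5, 7.5, step = 0.01)
  expect_equal(nrow(band), 501L)
  expect_equal(band$grid_cm[1], 2.5)
  expect_equal(band$grid_cm[501], 7.5, tolerance = 1e-12)
  width <- band$upr_kg - band$lwr_kg
  expect_true(all(diff(width) > 0))  # positive slope, positive noise

  zero <- prediction_band(exact_fit(), 2.5, 7.5, step = 0.1)
  expect_equal(zero$upr_kg - zero$lwr_kg, rep(0, nrow(zero)), tolerance = 1e-6)

  expect_error(prediction_band(fit, 5, 2), "less than")
})

test_that("band overlap matches interval arithmetic", {
  g <- seq(2.5, 7.5, by = 0.5)
  a <- make_band(g, lwr = 0, upr = 2)
  b <- make_band(g, lwr = 1, upr = 3)
  expect_equal(band_overlap(a, a), 1)
  expect_equal(band_overlap(a, b), 0.5)
  disjoint <- make_band(g, lwr = 5, upr = 6)
  expect_equal(band_overlap(a, disjoint), 0)
  expect_error(band_overlap(a, make_band(g + 1, 0, 2)), "identical")
})

test_that("tip and whole-shrub bands from a shared self-similar law overlap", {
  # two calibrations drawn from the same power law should yield bands whose
  # mean fractional overlap is high (the self-similarity diagnostic)
  set.seed(7)
  gen <- function(n) {
    d <- runif(n, 2.5, 7.5)
    tibble::tibble(diameter_cm = d, mass_kg = 0.07 * d^2.437 * exp(rnorm(n, 0, 0.45)))
  }
  band_tip <- prediction_band(fit_loglog(gen(95)), 2.5, 7.5, step = 0.05)
  band_whole <- prediction_band(fit_loglog(gen(37)), 2.5, 7.5, step = 0.05)
  expect_gt(band_overlap(band_tip, band_whole), 0.8)
})

test_that("the prediction-error allometry is recovered from band widths", {
  # widths exactly 3 * D^2.1
  g <- seq(2, 12, by = 0.5)
  w <- 3 * g^2.1
  band <- make_band(g, lwr = 10 - w / 2, upr = 10 + w / 2)
  pe <- fit_pe_model(band)
  expect_equal(pe$k, 3, tolerance = 1e-10)
  expect_equal(pe$p, 2.1, tolerance = 1e-10)

  # two-point exact solve: (1, 2) and (e, 2e) gives k = 2, p = 1
  g2 <- c(1, exp(1))
  w2 <- c(2, 2 * exp(1))
  band2 <- make_band(g2, lwr = 5 - w2 / 2, upr = 5 + w2 / 2)
  pe2 <- fit_pe_model(band2)
  expect_equal(pe2$k, 2, tolerance = 1e-10)
  expect_equal(pe2$p, 1, tolerance = 1e-10)

  zero <- make_band(g, lwr = 1, upr = 1)
  expect_error(fit_pe_model(zero), "positive")
})

test_that("tidy and glance expose the fit summaries", {
  fit <- four_point_fit()
  td <- tidy(fit)
  expect_equal(td$estimate, c(0.97, 2.52), tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$nobs, 4L)
  expect_equal(gl$df.residual, 2L)
})
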