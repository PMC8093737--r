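test_that("the diameter kernel density is normalized, smooth and deterministic", {
  set.seed(21)
  x <- rnorm(1e5, 10, 2)
  x <- x[x > 0]
  dens <- kde_diameters(x)
  expect_equal(nrow(dens), 512L)
  expect_true(all(diff(dens$x) > 0))
  # Riemann normalization with the dx = range/512 convention
  expect_lt(abs(sum(dens$y) * attr(dens, "dx") - 1), 0.02)
  # density at the mode of a normal(10, 2) is 1/(2 sqrt(2 pi))
  y_at_10 <- dens$y[which.min(abs(dens$x - 10))]
  expect_lt(abs(y_at_10 - 1 / (2 * sqrt(2 * pi))) / (1 / (2 * sqrt(2 * pi))), 0.03)
  # no randomness: identical inputs give identical grids
  expect_identical(kde_diameters(x), dens)
  expect_error(kde_diameters(c(2, 2, 2)), "distinct")
  expect_error(kde_diameters(c(-1, 3)), "positive")
})

test_that("expected prediction error matches closed forms and quadrature", {
  # uniform density on [2.5, 7.5], k = 1, p = 2.4:
  # integral = (7.5^3.4 - 2.5^3.4) / (3.4 * 5)
  dens <- uniform_density(2.5, 7.5)
  pe <- pe_model(1, 2.4)
  closed <- (7.5^3.4 - 2.5^3.4) / (3.4 * 5)
  expect_lt(abs(expected_pe(dens, pe) - closed) / closed, 0.005)

  # against adaptive quadrature on a smooth kernel density
  set.seed(4)
  d <- rlnorm(2000, log(5), 0.5)
  kd <- kde_diameters(d)
  pe2 <- pe_model(exp(-2.02), 2.41)
  f <- approxfun(kd$x, kd$y, yleft = 0, yright = 0)
  oracle <- integrate(function(x) f(x) * pe2$k * x^pe2$p,
                      lower = max(0, min(kd$x)), upper = max(kd$x),
                      subdivisions = 1000L)$value
  riemann <- expected_pe(kd, pe2)
  expect_lt(abs(riemann - oracle) / oracle, 0.01)

  # restricting to the grid maximum reproduces the full integral exactly
  expect_identical(expected_pe(kd, pe2, upper_cm = max(kd$x)),
                   expected_pe(kd, pe2))
  # E[PE2] is nondecreasing in the threshold and bounded by E[PE1]
  epe2 <- vapply(c(4, 6, 8, 10, 14), function(u) expected_pe(kd, pe2, u),
                 numeric(1))
  expect_true(all(diff(epe2) >= 0))
  expect_true(all(epe2 <= expected_pe(kd, pe2) + 1e-12))
  # cut-off below the whole grid integrates to nothing
  expect_warning(res <- expected_pe(kd, pe2, upper_cm = min(kd$x) - 1), "below")
  expect_equal(res, 0)
  # scale consistency: multiplying k scales both integrals equally
  pe3 <- pe_model(5 * pe2$k, pe2$p)
  expect_equal(expected_pe(kd, pe3, 10) / expected_pe(kd, pe3),
               expected_pe(kd, pe2, 10) / expected_pe(kd, pe2),
               tolerance = 1e-12)
})

test_that("time-cost regression recovers coefficients and validates its design", {
  rec <- tibble::tibble(
    n_single = c(40, 80, 120, 60, 100),
    n_two = c(2, 10, 5, 8, 3),
    total_time_s = 300 + 26 * n_single + 111 * n_two
  )
  fit <- fit_time_cost(rec)
  expect_equal(c(fit$t0_s, fit$t1_s, fit$t2_s), c(300, 26, 111),
               tolerance = 1e-8)
  expect_equal(fit$sigma_s, 0, tolerance = 1e-6)

  # noisy 5-plot dataset against the closed-form normal equations
  rec2 <- dplyr::mutate(rec, total_time_s = total_time_s + c(200, -150, 90, -60, 310))
  fit2 <- fit_time_cost(rec2)
  ora <- mlr_oracle(rec2$n_single, rec2$n_two, rec2$total_time_s)
  expect_equal(c(fit2$t0_s, fit2$t1_s, fit2$t2_s), ora, tolerance = 1e-8)

  expect_error(fit_time_cost(rec[1:3, ]), "At least 4")
  expect_error(
    fit_time_cost(tibble::tibble(n_single = c(1, 2, 3, 4),
                                 n_two = c(2, 4, 6, 8),
                                 total_time_s = c(100, 200, 300, 400))),
    "rank"
  )
})

test_that("the benefit/cost rule evaluates candidates as derived", {
  # no stems above the threshold: two-component costs nothing extra
  free <- evaluate_dmax(pe_ratio = 1.0, t1_s = 26, t2_s = 111, p_exceed = 0)
  expect_equal(free$time_ratio, 1)
  expect_true(free$acceptable)

  # direct arithmetic: (111 * 0.2 + 26) / 26 = 1.8538... > 1.2
  rej <- evaluate_dmax(pe_ratio = 1.2, t1_s = 26, t2_s = 111, p_exceed = 0.2)
  expect_equal(rej$time_ratio, (111 * 0.2 + 26) / 26, tolerance = 1e-12)
  expect_false(rej$acceptable)

  expect_error(evaluate_dmax(1.2, t1_s = 0, t2_s = 111, p_exceed = 0.1),
               "positive")
  expect_error(evaluate_dmax(1.2, t1_s = 26, t2_s = 111, p_exceed = 1.2),
               "0, 1")
})

test_that("scanning candidates yields monotone ratios and a feasible boundary", {
  set.seed(31)
  diam <- rlnorm(1286, log(5), 0.5)
  pe <- pe_model(exp(-2.02), 2.41)
  time_fit <- fit_time_cost(tibble::tibble(
    n_single = c(40, 80, 120, 60, 100),
    n_two = c(2, 10, 5, 8, 3),
    total_time_s = 300 + 26 * n_single + 111 * n_two
  ))
  cands <- c(4, 6, 8, 10, 12, max(diam))
  scan <- scan_dmax(diam, pe, time_fit, cands)
  expect_equal(nrow(scan), length(cands))
  expect_equal(scan$d_max_cm, cands)
  expect_true(all(diff(scan$pe_ratio) <= 1e-12))
  expect_true(all(diff(scan$time_ratio) <= 1e-12))
  expect_true(all(scan$epe2_kg <= scan$epe1_kg + 1e-12))
  expect_true(all(scan$pe_ratio >= 1))
  # the largest observed diameter costs no extra time and is acceptable
  top <- scan[nrow(scan), ]
  expect_equal(top$p_exceed, 0)
  expect_equal(top$time_ratio, 1)
  expect_true(top$acceptable)

  expect_error(scan_dmax(diam, pe, time_fit, numeric(0)), "At least one")
  expect_error(scan_dmax(diam, pe, time_fit, max(diam) + 1), "range")
})
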