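test_that("the field algorithm decomposes hand-built shrubs correctly", {
  # Step 3 stop: a single small stem is one tip
  tip_only <- decompose(stem_segment(5), d_min = 2.5, d_max = 7.5)
  expect_equal(tip_only$kind, "tip")
  expect_equal(tip_only$d1_cm, 5)

  # below the tall-shrub minimum: excluded entirely
  expect_equal(nrow(decompose(stem_segment(2.0), d_min = 2.5, d_max = 7.5)), 0L)

  # branching shrub: basal frustum plus two tips
  shrub <- stem_segment(12, top_diameter_cm = 6, length_cm = 80,
                        children = list(stem_segment(5), stem_segment(4)))
  comps <- decompose(shrub, 2.5, 7.5)
  expect_equal(comps$kind, c("frustum", "tip", "tip"))
  expect_equal(comps$d1_cm, c(12, 5, 4))
  expect_equal(comps$d2_cm[1], 6)
  expect_equal(comps$length_cm[1], 80)

  # unbranched chain 20 ->(100)-> 9 ->(60)-> 5
  chain <- stem_segment(20, 9, 100, children = list(
    stem_segment(9, 5, 60, children = list(stem_segment(5)))
  ))
  comps2 <- decompose(chain, 2.5, 7.5)
  expect_equal(comps2$kind, c("frustum", "frustum", "tip"))
  expect_equal(comps2$d1_cm, c(20, 9, 5))
  expect_equal(comps2$d2_cm[1:2], c(9, 5))
  expect_equal(comps2$length_cm[1:2], c(100, 60))

  # the tie case D1 == d_max is a tip, exactly as the stopping rule reads
  expect_equal(decompose(stem_segment(7.5), 2.5, 7.5)$kind, "tip")

  # a large stem missing frustum measurements is malformed
  expect_error(decompose(stem_segment(12), 2.5, 7.5), "lacks")
})

test_that("multi-stemmed shrubs decompose per root-collar stem", {
  shrub <- list(
    stem_segment(6),
    stem_segment(2.0),   # below d_min, dropped
    stem_segment(10, 5, 70, children = list(stem_segment(5)))
  )
  comps <- decompose(shrub, 2.5, 7.5)
  expect_equal(comps$kind, c("tip", "frustum", "tip"))
  expect_equal(comps$d1_cm, c(6, 10, 5))
})

test_that("decomposition tiles simulated shrubs and is monotone in d_max", {
  cfg <- small_config()
  for (seed in 1:5) {
    shrub <- gen_shrub(cfg, seed = seed, drc = 15 + seed)
    # conservation: components carry every segment's true mass exactly once
    sum_true <- function(seg) {
      own <- if (is.null(seg$true_mass_kg)) 0 else seg$true_mass_kg
      own + sum(vapply(seg$children, sum_true, numeric(1)))
    }
    comps <- decompose(shrub, cfg$d_min, cfg$d_max)
    expect_equal(sum(comps$true_mass_kg), sum_true(shrub), tolerance = 1e-10)
    # components tile the structure also at a coarser threshold, where a
    # tip swallows a whole subtree
    comps10 <- decompose(shrub, cfg$d_min, 10)
    expect_equal(sum(comps10$true_mass_kg), sum_true(shrub), tolerance = 1e-10)
    # raising d_max never increases the number of frustra (thresholds at or
    # above the generation threshold, where all measurements exist)
    n_frus <- vapply(c(7.5, 10, 15, 25), function(dm) {
      sum(decompose(shrub, cfg$d_min, dm)$kind == "frustum")
    }, numeric(1))
    expect_true(all(diff(n_frus) <= 0))
  }
})

test_that("component estimates compose the fitted models exactly", {
  tip_fit <- exact_fit(a = 0.07, b = 2.437, d = c(2.5, 5, 7.5))
  v <- c(1, 2, 4)
  d_cyl <- sqrt(v * 1000 * 4 / (pi * 100))
  internode_fit <- fit_density_loglog(tibble::tibble(
    d1_cm = d_cyl, d2_cm = d_cyl, length_cm = 100, mass_kg = 0.9 * v
  ))
  comps <- tibble::tibble(
    kind = c("tip", "frustum"),
    d1_cm = c(5, 12), d2_cm = c(NA, 8), length_cm = c(NA, 100)
  )
  est <- estimate_components(comps, tip_fit, internode_fit)
  expect_equal(est$point_kg[1], 0.07 * 5^2.437, tolerance = 1e-8)
  v_f <- frustum_volume(12, 8, 100) / 1000
  expect_equal(est$point_kg[2], 0.9 * v_f, tolerance = 1e-8)
  expect_equal(est$se_log, c(0, 0), tolerance = 1e-6)

  # empty component list passes through as an empty estimate table
  empty <- estimate_components(comps[0, ], tip_fit, internode_fit)
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("mu_log", "se_log", "point_kg") %in% names(empty)))

  # tips beyond the calibration range warn about extrapolation
  expect_warning(
    estimate_components(tibble::tibble(kind = "tip", d1_cm = 9, d2_cm = NA,
                                       length_cm = NA),
                        tip_fit, internode_fit),
    "extrapolation"
  )
})

test_that("tip estimates reuse the verified prediction machinery", {
  fit <- four_point_fit()
  internode_fit <- fit_density_loglog(tibble::tibble(
    d1_cm = c(3, 4, 6), d2_cm = c(3, 4, 6), length_cm = 100,
    mass_kg = 0.9 * frustum_volume(c(3, 4, 6), c(3, 4, 6), 100) / 1000
  ))
  est <- suppressWarnings(estimate_components(
    tibble::tibble(kind = "tip", d1_cm = exp(1.5), d2_cm = NA, length_cm = NA),
    fit, internode_fit
  ))
  expect_equal(est$mu_log, 4.75, tolerance = 1e-10)
  expect_equal(est$se_log, sqrt(0.01125), tolerance = 1e-10)
})

test_that("single-component estimates are order-preserving and coincide with all-tip decompositions", {
  fit <- exact_fit(a = 0.07, b = 2.437, d = c(2.5, 5, 7.5))
  drc <- c(3, 6, 4.5)
  est <- single_component_estimates(drc, fit)
  expect_equal(nrow(est), 3L)
  expect_equal(est$drc_cm, drc)
  expect_equal(est$point_kg, 0.07 * drc^2.437, tolerance = 1e-10)

  # a shrub at or below d_max decomposes to one tip: with a shared fit the
  # two methods give identical estimates (self-similarity consistency)
  comps <- decompose(stem_segment(6), 2.5, 7.5)
  two <- estimate_components(comps, fit, fit_density_loglog(tibble::tibble(
    d1_cm = c(3, 4, 6), d2_cm = c(3, 4, 6), length_cm = 100,
    mass_kg = 0.9 * frustum_volume(c(3, 4, 6), c(3, 4, 6), 100) / 1000
  )))
  one <- single_component_estimates(6, fit)
  expect_equal(two$mu_log, one$mu_log, tolerance = 1e-12)
  expect_equal(two$se_log, one$se_log, tolerance = 1e-12)

  expect_error(single_component_estimates(c(3, -1), fit), "positive")
})
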