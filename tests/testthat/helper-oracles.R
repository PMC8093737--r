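# Fixtures and independent oracles used across the suite. Oracles are
# deliberately written from first principles (normal equations, closed-form
# lognormal moments) so they share no code with the implementation.

# Closed-form simple OLS via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  list(
    intercept = intercept,
    slope = slope,
    residual_scale = sqrt(sum(resid^2) / (n - 2)),
    slope_se = sqrt(sum(resid^2) / (n - 2) / sxx)
  )
}

# Closed-form two-predictor OLS (intercept + 2 slopes) via solve(X'X, X'y).
mlr_oracle <- function(x1, x2, y) {
  X <- cbind(1, x1, x2)
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Fit on ln D = 0:3, ln M = (1.0, 3.4, 6.1, 8.5); hand-solved values:
# slope 2.52, intercept 0.97, residual scale sqrt(0.018/2).
four_point_fit <- function() {
  fit_loglog(tibble::tibble(
    diameter_cm = exp(0:3),
    mass_kg = exp(c(1.0, 3.4, 6.1, 8.5))
  ))
}

# Noiseless power-law calibration M = a * D^b.
exact_fit <- function(a = 2, b = 2.5, d = c(2, 4, 8)) {
  fit_loglog(tibble::tibble(diameter_cm = d, mass_kg = a * d^b))
}

# A prediction_band with specified bounds at every grid point (for overlap
# and PE-model tests).
make_band <- function(grid, lwr, upr, point = (lwr + upr) / 2, level = 0.95) {
  out <- tibble::tibble(
    grid_cm = grid,
    point_kg = rep_len(point, length(grid)),
    lwr_kg = rep_len(lwr, length(grid)),
    upr_kg = rep_len(upr, length(grid))
  )
  structure(out, level = level, step = if (length(grid) > 1) diff(grid[1:2]) else NA,
            class = c("prediction_band", class(out)))
}

# A uniform diameter density on [lo, hi] in the package's grid format.
uniform_density <- function(lo, hi, n = 512) {
  x <- seq(lo, hi, length.out = n)
  out <- tibble::tibble(x = x, y = rep(1 / (hi - lo), n))
  structure(out, dx = (hi - lo) / n, bw = NA, n = NA,
            class = c("diameter_density", class(out)))
}

# Small simulator configuration for fast end-to-end tests (study-scale
# parameters, reduced plot size only).
small_config <- function(...) {
  sim_config(plot_shrub_mean = 8, ...)
}
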