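#' Fit a power-function allometry on the log-log scale
#'
#' Fits `ln(M) = b ln(D) + ln(a)` by ordinary least squares, the standard way
#' biomass-diameter allometries are estimated when residuals are
#' multiplicative (heteroscedastic on the arithmetic scale, homoscedastic
#' after log transform). The returned object stores everything needed to
#' compute estimation and prediction standard errors at new diameters:
#' the residual scale `sqrt(SSE / (n - 2))`, the mean of the log predictor,
#' and its sum of squared deviations.
#'
#' @param data A data frame of calibration samples, one row per destructively
#'   weighed shrub or aerial tip.
#' @param diameter,mass Unquoted column names holding stem diameter (cm) and
#'   wet field-mass (kg). Defaults match the calibration CSV schema.
#' @param predictor,response Labels recorded on the fit (used for column
#'   naming in predictions and for extrapolation warnings).
#'
#' @return An object of class `loglog_fit`: a list with elements `intercept`
#'   (ln a), `slope` (exponent b), `residual_scale`, `n`, `df`, `mean_logx`,
#'   `sxx`, `r2`, `slope_se`, `intercept_se`, and `x_range` (the natural-scale
#'   predictor range of the training data).
#' @seealso [predict_log()], [prediction_interval()], [prediction_band()]
#' @examples
#' cal <- tibble::tibble(diameter_cm = c(2, 4, 8), mass_kg = 2 * c(2, 4, 8)^2.5)
#' fit <- fit_loglog(cal)
#' c(a = exp(fit$intercept), b = fit$slope)
#' @export
fit_loglog <- function(data, diameter = diameter_cm, mass = mass_kg,
                       predictor = "diameter_cm", response = "mass_kg") {
  x <- dplyr::pull(data, {{ diameter }})
  y <- dplyr::pull(data, {{ mass }})
  loglog_ols(x, y, predictor = predictor, response = response)
}

# Shared OLS core for log-log fits (tip/whole allometry and the internode
# mass-volume model both come through here).
loglog_ols <- function(x, y, predictor, response, extra = list()) {
  if (length(x) < 3L) {
    abort("At least 3 calibration samples are required.")
  }
  check_positive(x, predictor)
  check_positive(y, response)
  if (length(unique(x)) < 2L) {
    abort("Calibration samples must contain at least 2 distinct predictor values.")
  }
  lx <- log(x)
  ly <- log(y)
  fit <- lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # noiseless calibration is legitimate
  n <- length(x)
  out <- list(
    intercept      = unname(coef(fit)[1L]),
    slope          = unname(coef(fit)[2L]),
    residual_scale = if (n > 2L) sm$sigma else 0,
    n              = n,
    df             = n - 2L,
    mean_logx      = mean(lx),
    sxx            = sum((lx - mean(lx))^2),
    r2             = sm$r.squared,
    slope_se       = unname(sm$coefficients[2L, 2L]),
    intercept_se   = unname(sm$coefficients[1L, 2L]),
    x_range        = range(x),
    predictor      = predictor,
    response       = response
  )
  out <- c(out, extra)
  structure(out, class = "loglog_fit")
}

#' Expected log-mass and its standard errors at new predictor values
#'
#' For a fitted log-log allometry, returns the expected log response
#' `mu = intercept + slope * ln(x)` together with the estimation standard
#' error `se_fit = residual_scale * sqrt(1/n + (ln x - mean_logx)^2 / sxx)`
#' and the prediction standard error
#' `se_pred = sqrt(residual_scale^2 + se_fit^2)`, i.e. regression error of
#' the estimate combined in quadrature with the residual standard error.
#'
#' @param fit A [loglog_fit][fit_loglog()].
#' @param x Positive predictor values on the natural scale (diameter in cm
#'   for allometric fits, frustum volume in litres for internode fits).
#' @return A tibble with the predictor column, `mu_log`, `se_fit`, `se_pred`.
#' @export
predict_log <- function(fit, x) {
  stopifnot(inherits(fit, "loglog_fit"))
  check_positive(x, fit$predictor)
  lx <- log(x)
  mu <- fit$intercept + fit$slope * lx
  se_fit <- fit$residual_scale * sqrt(1 / fit$n + (lx - fit$mean_logx)^2 / fit$sxx)
  tibble::tibble(
    !!fit$predictor := x,
    mu_log  = mu,
    se_fit  = se_fit,
    se_pred = sqrt(fit$residual_scale^2 + se_fit^2)
  )
}

#' Back-transformed prediction interval for an individual mass
#'
#' Computes the point estimate `a * D^b` and the back-transformed prediction
#' interval `exp(mu -/+ t_{df, 1-(1-level)/2} * se_pred)`. On the arithmetic
#' scale the interval is multiplicatively symmetric (`lwr * upr = point^2`)
#' and therefore positively skewed about the point estimate, which is the
#' expected behaviour for lognormal prediction error.
#'
#' @inheritParams predict_log
#' @param level Confidence level of the interval, in (0, 1).
#' @return A tibble with the predictor column, `point_kg`, `lwr_kg`, `upr_kg`.
#' @export
prediction_interval <- function(fit, x, level = 0.95) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1).")
  }
  if (fit$df < 1L) {
    abort("Prediction intervals require at least 1 residual degree of freedom.")
  }
  p <- predict_log(fit, x)
  tcrit <- qt(1 - (1 - level) / 2, df = fit$df)
  half <- tcrit * p$se_pred
  tibble::tibble(
    !!fit$predictor := x,
    point_kg = exp(p$mu_log),
    lwr_kg   = exp(p$mu_log - half),
    upr_kg   = exp(p$mu_log + half)
  )
}

#' Prediction band over a regular diameter grid
#'
#' Evaluates [prediction_interval()] on the inclusive grid from `d_min` to
#' `d_max` in steps of `step` (0.01 cm by default, the resolution used to
#' quantify uncertainty across the tip range 2.5-7.5 cm).
#'
#' @inheritParams prediction_interval
#' @param d_min,d_max Grid endpoints in cm, `d_min < d_max`.
#' @param step Grid increment in cm.
#' @return A tibble of class `prediction_band` with columns `grid_cm`,
#'   `point_kg`, `lwr_kg`, `upr_kg`; the confidence level and step are kept
#'   as attributes.
#' @export
prediction_band <- function(fit, d_min = 2.5, d_max = 7.5, step = 0.01,
                            level = 0.95) {
  if (!(d_min < d_max)) abort("`d_min` must be less than `d_max`.")
  check_positive(step, "step")
  n_pts <- round((d_max - d_min) / step) + 1L
  if (n_pts < 1L) abort("Empty grid.")
  grid <- d_min + step * (seq_len(n_pts) - 1)
  pi <- prediction_interval(fit, grid, level = level)
  out <- tibble::tibble(
    grid_cm  = grid,
    point_kg = pi$point_kg,
    lwr_kg   = pi$lwr_kg,
    upr_kg   = pi$upr_kg
  )
  structure(out, level = level, step = step,
            class = c("prediction_band", class(out)))
}

#' Mean fractional overlap of two prediction bands
#'
#' Quantifies how completely one allometry's prediction band is contained in
#' another's, as the grid mean of
#' `length([lwr_a, upr_a] intersect [lwr_b, upr_b]) / length([lwr_a, upr_a])`.
#' An overlap near 1 for a tip band (`band_a`) against a whole-shrub band
#' (`band_b`) is the self-similarity signature: one regression suffices for
#' parts and wholes.
#'
#' At grid points where `band_a` has zero width (a noiseless fit) the ratio
#' degenerates; there the contribution is 1 if the point estimate of `band_a`
#' lies inside `band_b`'s interval and 0 otherwise.
#'
#' @param band_a,band_b [prediction_band()] objects on identical grids.
#' @return A single fraction in \[0, 1\].
#' @export
band_overlap <- function(band_a, band_b) {
  stopifnot(inherits(band_a, "prediction_band"), inherits(band_b, "prediction_band"))
  if (nrow(band_a) != nrow(band_b) ||
      !isTRUE(all.equal(band_a$grid_cm, band_b$grid_cm))) {
    abort("Bands must share an identical diameter grid.")
  }
  width_a <- band_a$upr_kg - band_a$lwr_kg
  inter <- pmax(0, pmin(band_a$upr_kg, band_b$upr_kg) -
                   pmax(band_a$lwr_kg, band_b$lwr_kg))
  frac <- ifelse(
    width_a > 0,
    inter / width_a,
    as.numeric(band_a$point_kg >= band_b$lwr_kg & band_a$point_kg <= band_b$upr_kg)
  )
  mean(frac)
}

#' Prediction-error allometry
#'
#' Prediction error (the range `upr - lwr` of the 95% PI) itself scales as a
#' power function of diameter, `PE = k * D^p`. `fit_pe_model()` recovers
#' `(k, p)` by regressing `log(width)` on `log(diameter)` over a prediction
#' band; `pe_model()` constructs the model directly from known coefficients
#' (e.g. values reported from a prior calibration).
#'
#' @param band A [prediction_band()] with strictly positive widths.
#' @return An object of class `pe_model`: a list with elements `k` and `p`.
#' @export
fit_pe_model <- function(band) {
  stopifnot(inherits(band, "prediction_band"))
  width <- band$upr_kg - band$lwr_kg
  if (any(width <= 0)) {
    abort("All band widths must be positive to fit the prediction-error allometry.")
  }
  fit <- lm(log(width) ~ log(band$grid_cm))
  pe_model(k = exp(unname(coef(fit)[1L])), p = unname(coef(fit)[2L]))
}

#' @rdname fit_pe_model
#' @param k,p Positive scale factor and exponent of `PE = k * D^p`.
#' @export
pe_model <- function(k, p) {
  check_positive(k, "k")
  check_positive(p, "p")
  structure(list(k = k, p = p), class = "pe_model")
}

#' @export
print.pe_model <- function(x, ...) {
  cat(sprintf("Prediction-error allometry: PE = %.4g * D^%.4g\n", x$k, x$p))
  invisible(x)
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "Log-log power-function fit: %s = %.4g * %s^%.4g\n  n = %d, residual scale = %.4g, R^2 = %.3f\n",
    x$response, exp(x$intercept), x$predictor, x$slope, x$n, x$residual_scale, x$r2
  ))
  invisible(x)
}

#' @export
tidy.loglog_fit <- function(x, ...) {
  tibble::tibble(
    term      = c("intercept_log", "slope"),
    estimate  = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.loglog_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, sigma = x$residual_scale,
    nobs = x$n, df.residual = x$df
  )
}

#' @export
autoplot.prediction_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid_cm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lwr_kg, ymax = .data$upr_kg),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point_kg), colour = "steelblue4") +
    ggplot2::labs(
      x = "Stem diameter (cm)", y = "Wet field-mass (kg)",
      title = sprintf("Allometric point estimate with %g%% prediction band",
                      100 * attr(object, "level"))
    )
}
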