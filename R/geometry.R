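#' Volume of a conic frustum stem internode
#'
#' A stem internode with end diameters `d1`, `d2` and length `L` is modelled
#' as a regular conic frustum with volume
#' `V = pi * L * (d1^2 + d1*d2 + d2^2) / 12` (cm^3 when inputs are in cm).
#' The formula is symmetric in the two diameters and covers the cylinder
#' (`d1 == d2`) and cone (`d2 == 0`) limits. Divide by 1000 for litres.
#'
#' @param d1_cm,d2_cm End diameters in cm, non-negative and not both zero.
#' @param length_cm Internode length in cm, strictly positive.
#' @return Volume in cm^3 (vectorised over the inputs).
#' @examples
#' frustum_volume(12, 8, 100)            # ~ 7958.7 cm^3
#' frustum_volume(10, 10, 100) / 1000    # cylinder, in litres
#' @export
frustum_volume <- function(d1_cm, d2_cm, length_cm) {
  if (!is.numeric(d1_cm) || !is.numeric(d2_cm) || anyNA(d1_cm) || anyNA(d2_cm) ||
      any(d1_cm < 0) || any(d2_cm < 0)) {
    abort("Frustum diameters must be numeric and non-negative.")
  }
  n <- max(length(d1_cm), length(d2_cm), length(length_cm))
  d1 <- rep_len(d1_cm, n); d2 <- rep_len(d2_cm, n); L <- rep_len(length_cm, n)
  if (any(d1 == 0 & d2 == 0)) abort("Frustum diameters must not both be zero.")
  check_positive(L, "length_cm")
  # grouped so the expression is bit-exactly symmetric in (d1, d2)
  pi * L * ((d1 * d1 + d2 * d2) + d1 * d2) / 12
}

#' Wet density from a weighed, submerged stem piece
#'
#' Direct wet-density measurement: field mass divided by volume determined
#' by water displacement.
#'
#' @param mass_kg Wet field-mass in kg.
#' @param volume_L Displacement volume in litres.
#' @return Density in kg/L (vectorised).
#' @examples
#' wet_density(3.49, 4.73)  # 0.74 kg/L
#' @export
wet_density <- function(mass_kg, volume_L) {
  check_positive(mass_kg, "mass_kg")
  check_positive(volume_L, "volume_L")
  mass_kg / volume_L
}

internode_volume_L <- function(data) {
  check_columns(data, c("d1_cm", "d2_cm", "length_cm", "mass_kg"),
                "internode data")
  frustum_volume(data$d1_cm, data$d2_cm, data$length_cm) / 1000
}

#' Calibrate internode mass against frustum volume
#'
#' Two forms of the internode mass-volume calibration:
#'
#' * `fit_density_linear()` regresses mass (kg) on frustum volume (L) with a
#'   free intercept; the slope is the wet-density estimate (kg/L) with its
#'   standard error, directly comparable to displacement measurements.
#' * `fit_density_loglog()` regresses `ln(mass)` on `ln(volume)`. A slope of
#'   one indicates proportionality through the origin, in which case the
#'   intercept is the log wet-density; this form also stabilises the
#'   heteroscedastic residuals of the linear fit and is the default mass
#'   model for internodes in the two-component estimator.
#'
#' @param data A data frame of destructively sampled internodes with columns
#'   `d1_cm`, `d2_cm`, `length_cm`, `mass_kg` (see [read_internodes_csv()]).
#' @return An object of class `density_fit`. The log-log form also inherits
#'   `loglog_fit` (predictor `volume_L`), so [predict_log()] and
#'   [prediction_interval()] apply to it unchanged.
#' @export
fit_density_linear <- function(data) {
  v <- internode_volume_L(data)
  m <- data$mass_kg
  if (length(m) < 3L) abort("At least 3 internode samples are required.")
  check_positive(m, "mass_kg")
  if (length(unique(v)) < 2L) abort("Internode volumes have no spread.")
  fit <- lm(m ~ v)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      form = "linear",
      slope = unname(coef(fit)[2L]),
      slope_se = unname(sm$coefficients[2L, 2L]),
      intercept = unname(coef(fit)[1L]),
      intercept_se = unname(sm$coefficients[1L, 2L]),
      n = length(m), df = length(m) - 2L,
      r2 = sm$r.squared, residual_scale = sm$sigma
    ),
    class = "density_fit"
  )
}

#' @rdname fit_density_linear
#' @export
fit_density_loglog <- function(data) {
  v <- internode_volume_L(data)
  m <- data$mass_kg
  out <- loglog_ols(v, m, predictor = "volume_L", response = "mass_kg",
                    extra = list(form = "loglog"))
  class(out) <- c("density_fit", class(out))
  out
}

#' Confidence interval for wet density from the log-log intercept
#'
#' When the log-log mass-volume slope is ~1, the exponentiated intercept is
#' the wet density and its t-based confidence interval is
#' `exp(intercept -/+ t_{df, 1-(1-level)/2} * intercept_se)` in kg/L.
#'
#' @param fit Either a log-log [density fit][fit_density_loglog()] or a
#'   numeric intercept (log kg/L), in which case `intercept_se` and `df`
#'   must be supplied.
#' @param intercept_se,df Standard error of the intercept and residual
#'   degrees of freedom (ignored when `fit` is a fit object).
#' @param level Confidence level.
#' @return A one-row tibble: `density_kg_L`, `ci_lwr_kg_L`, `ci_upr_kg_L`,
#'   `level`.
#' @examples
#' density_ci(-0.0906, intercept_se = 0.057, df = 38)
#' @export
density_ci <- function(fit, intercept_se = NULL, df = NULL, level = 0.95) {
  if (inherits(fit, "density_fit")) {
    if (!identical(fit$form, "loglog")) {
      abort("`density_ci()` applies to the log-log density fit.")
    }
    intercept <- fit$intercept
    intercept_se <- fit$intercept_se
    df <- fit$df
  } else {
    intercept <- fit
    if (is.null(intercept_se) || is.null(df)) {
      abort("Supply `intercept_se` and `df` with a numeric intercept.")
    }
  }
  check_positive(intercept_se, "intercept_se")
  if (df < 1L) abort("`df` must be at least 1.")
  tcrit <- qt(1 - (1 - level) / 2, df = df)
  tibble::tibble(
    density_kg_L = exp(intercept),
    ci_lwr_kg_L  = exp(intercept - tcrit * intercept_se),
    ci_upr_kg_L  = exp(intercept + tcrit * intercept_se),
    level        = level
  )
}

#' @export
print.density_fit <- function(x, ...) {
  if (identical(x$form, "linear")) {
    cat(sprintf(
      "Internode wet-density (linear): slope = %.3f +/- %.3f kg/L, R^2 = %.3f, n = %d\n",
      x$slope, x$slope_se, x$r2, x$n
    ))
  } else {
    cat(sprintf(
      "Internode mass-volume (log-log): slope = %.4f (se %.4f), intercept = %.4f (se %.4f), n = %d\n",
      x$slope, x$slope_se, x$intercept, x$intercept_se, x$n
    ))
  }
  invisible(x)
}

#' @export
tidy.density_fit <- function(x, ...) {
  tibble::tibble(
    term      = c("intercept", "slope"),
    estimate  = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @export
glance.density_fit <- function(x, ...) {
  tibble::tibble(
    form = x$form, r.squared = x$r2, sigma = x$residual_scale,
    nobs = x$n, df.residual = x$df
  )
}
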