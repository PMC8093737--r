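#' Kernel density of pilot stem diameters
#'
#' Gaussian kernel density estimate of the stem-diameter distribution used
#' to integrate the prediction-error allometry. The bandwidth is the
#' classical rule of thumb `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, the grid is
#' 512 equispaced points extending 3 bandwidths beyond the data range
#' (optionally clipped at zero), and Riemann sums over the grid use
#' `dx = (max(x) - min(x)) / 512`.
#'
#' @param diameters Positive stem diameters (cm), at least 2 distinct values.
#' @param clip_zero If `TRUE`, the grid starts at 0 instead of extending
#'   below the smallest diameter.
#' @return A tibble of class `diameter_density` with columns `x` (cm) and
#'   `y` (density); attributes `dx`, `bw` and `n` record the Riemann
#'   increment, bandwidth, and sample size.
#' @export
kde_diameters <- function(diameters, clip_zero = FALSE) {
  check_positive(diameters, "diameters")
  if (length(diameters) < 2L || length(unique(diameters)) < 2L) {
    abort("At least 2 distinct diameters are required for a kernel density.")
  }
  dens <- if (clip_zero) {
    bw <- stats::bw.nrd0(diameters)
    density(diameters, n = 512, from = max(0, min(diameters) - 3 * bw))
  } else {
    density(diameters, n = 512)
  }
  out <- tibble::tibble(x = dens$x, y = dens$y)
  structure(out, dx = (max(dens$x) - min(dens$x)) / 512, bw = dens$bw,
            n = length(diameters),
            class = c("diameter_density", class(out)))
}

#' Expected per-stem prediction error
#'
#' Integrates the prediction-error allometry `PE = k * D^p` against the
#' stem-diameter density by the Riemann sum
#' `sum_i y_i * k * x_i^p * dx`. Over the full grid this is the expected
#' prediction error of a single-component measurement of a randomly sampled
#' stem, E\[PE1\]. Restricted to `x_i <= upper_cm` (the candidate `D_max`) it
#' is the two-component expectation E\[PE2\]: stems above the threshold are
#' measured as frustra, whose error is small enough to neglect, so only
#' stems below the threshold contribute allometric tip error.
#'
#' @param density A [kde_diameters()] result.
#' @param pe A [pe_model()].
#' @param upper_cm Optional integration cut-off (a candidate `D_max`, cm).
#'   Omit for E\[PE1\].
#' @return Expected prediction error in kg.
#' @export
expected_pe <- function(density, pe, upper_cm = NULL) {
  stopifnot(inherits(density, "diameter_density"), inherits(pe, "pe_model"))
  dx <- attr(density, "dx")
  # grid points leaked below zero by the kernel tail carry no physical PE
  sel <- density$x > 0
  if (!is.null(upper_cm)) {
    if (upper_cm < min(density$x)) {
      warn("`upper_cm` lies below the density grid; expected PE is 0.")
      return(0)
    }
    sel <- sel & density$x <= upper_cm
  }
  sum(density$y[sel] * pe$k * density$x[sel]^pe$p * dx)
}

#' Per-measurement time costs from pilot plot timings
#'
#' Multiple linear regression of total person-time per plot on the counts of
#' single- and two-component measurements:
#' `total_time = t0 + t1 * n_single + t2 * n_two + e`, `e ~ N(0, sigma^2)`.
#' `t1` and `t2` are the mean times of a single- and a two-component
#' measurement; `t0` absorbs per-plot overhead.
#'
#' @param records A data frame with columns `total_time_s`, `n_single`,
#'   `n_two`, one row per pilot plot; at least 4 plots and a full-rank
#'   design.
#' @return An object of class `time_cost_fit` with elements `t0_s`, `t1_s`,
#'   `t2_s`, `sigma_s`, `r2`, `n_plots`, plus `coef`, `xtx` and `df` for
#'   joint inference.
#' @export
fit_time_cost <- function(records) {
  check_columns(records, c("total_time_s", "n_single", "n_two"), "timing records")
  if (nrow(records) < 4L) abort("At least 4 timed plots are required.")
  fit <- lm(total_time_s ~ n_single + n_two, data = records)
  if (fit$qr$rank < 3L) {
    abort("Timing design is rank-deficient (collinear or constant counts).")
  }
  sm <- suppressWarnings(summary(fit))
  X <- stats::model.matrix(fit)
  structure(
    list(
      t0_s = unname(coef(fit)[1L]),
      t1_s = unname(coef(fit)[2L]),
      t2_s = unname(coef(fit)[3L]),
      sigma_s = sm$sigma,
      r2 = sm$r.squared,
      n_plots = nrow(records),
      coef = coef(fit),
      xtx = crossprod(X),
      df = fit$df.residual
    ),
    class = "time_cost_fit"
  )
}

#' @export
print.time_cost_fit <- function(x, ...) {
  cat(sprintf(
    "Time-cost regression over %d plots:\n  t0 = %.1f s, t1 = %.1f s (single), t2 = %.1f s (two-component)\n  residual sd = %.0f s, R^2 = %.3f\n",
    x$n_plots, x$t0_s, x$t1_s, x$t2_s, x$sigma_s, x$r2
  ))
  invisible(x)
}

#' @export
tidy.time_cost_fit <- function(x, ...) {
  tibble::tibble(term = c("t0_s", "t1_s", "t2_s"), estimate = unname(x$coef))
}

#' @export
glance.time_cost_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, sigma = x$sigma_s, nobs = x$n_plots,
                 df.residual = x$df)
}

#' Benefit/cost verdict for a candidate D_max
#'
#' The decision rule for the measurement threshold: adopting the
#' two-component protocol at a candidate `D_max` is worthwhile when the
#' precision gain at least matches the time cost,
#' `E[PE1]/E[PE2] >= (E[t2] + t1) / t1`, where `E[t2] = t2 * P(D > D_max)`
#' is the expected extra frustum-measurement time (every stem is first
#' measured once to decide whether it needs frustum measurements, hence the
#' added `t1`).
#'
#' @param pe_ratio Precision gain `E[PE1]/E[PE2]` (>= 1).
#' @param t1_s,t2_s Mean times of a single- and two-component measurement
#'   (seconds), `t1_s > 0`.
#' @param p_exceed Proportion of stems with diameter strictly greater than
#'   the candidate, in \[0, 1\].
#' @param d_max_cm,epe1_kg,epe2_kg Optional bookkeeping fields carried into
#'   the result (filled by [scan_dmax()]).
#' @return A one-row tibble of class `dmax_evaluation`: `d_max_cm`,
#'   `epe1_kg`, `epe2_kg`, `pe_ratio`, `p_exceed`, `e_t2_s`,
#'   `expected_two_time_s`, `time_ratio`, `acceptable`.
#' @examples
#' evaluate_dmax(pe_ratio = 1.4, t1_s = 26, t2_s = 111, p_exceed = 0.09)
#' @export
evaluate_dmax <- function(pe_ratio, t1_s, t2_s, p_exceed, d_max_cm = NA_real_,
                          epe1_kg = NA_real_, epe2_kg = NA_real_) {
  check_positive(t1_s, "t1_s")
  check_positive(t2_s, "t2_s")
  if (p_exceed < 0 || p_exceed > 1) abort("`p_exceed` must lie in [0, 1].")
  e_t2 <- t2_s * p_exceed
  expected_two <- e_t2 + t1_s
  time_ratio <- expected_two / t1_s
  out <- tibble::tibble(
    d_max_cm = d_max_cm,
    epe1_kg = epe1_kg,
    epe2_kg = epe2_kg,
    pe_ratio = pe_ratio,
    p_exceed = p_exceed,
    e_t2_s = e_t2,
    expected_two_time_s = expected_two,
    time_ratio = time_ratio,
    acceptable = pe_ratio >= time_ratio
  )
  structure(out, class = c("dmax_evaluation", class(out)))
}

#' Scan candidate D_max values
#'
#' Evaluates the benefit/cost rule over a set of candidate thresholds:
#' for each candidate, `p_exceed` is the empirical fraction of pilot
#' diameters strictly above it, and E\[PE1\]/E\[PE2\] come from
#' [expected_pe()] on the pilot kernel density. Lower candidates buy more
#' precision (larger `pe_ratio`) at more time (larger `time_ratio`); the
#' practical choice is the smallest convenient candidate still flagged
#' acceptable.
#'
#' @param diameters Pilot stem diameters (cm).
#' @param pe A [pe_model()].
#' @param time A [fit_time_cost()] result.
#' @param candidates Candidate `D_max` values (cm), within the observed
#'   diameter range.
#' @return A tibble of class `dmax_scan`, one [evaluate_dmax()] row per
#'   candidate, in candidate order.
#' @export
scan_dmax <- function(diameters, pe, time, candidates) {
  stopifnot(inherits(pe, "pe_model"), inherits(time, "time_cost_fit"))
  if (length(candidates) == 0L) abort("At least one candidate is required.")
  check_positive(candidates, "candidates")
  if (any(candidates < min(diameters) | candidates > max(diameters))) {
    abort("Candidates must lie within the observed diameter range.")
  }
  dens <- kde_diameters(diameters)
  epe1 <- expected_pe(dens, pe)
  rows <- purrr::map(candidates, function(cand) {
    epe2 <- expected_pe(dens, pe, upper_cm = cand)
    evaluate_dmax(
      pe_ratio = epe1 / epe2,
      t1_s = time$t1_s, t2_s = time$t2_s,
      p_exceed = mean(diameters > cand),
      d_max_cm = cand, epe1_kg = epe1, epe2_kg = epe2
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("dmax_scan", setdiff(class(out), "dmax_scan")))
}

#' @export
autoplot.dmax_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "d_max_cm", "pe_ratio", "time_ratio"),
    cols = c("pe_ratio", "time_ratio"),
    names_to = "quantity", values_to = "ratio"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d_max_cm, y = .data$ratio,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(Candidate ~ D[max] ~ (cm)), y = "Ratio",
      colour = NULL,
      title = "Precision gain vs time cost across candidate thresholds"
    )
}

#' @export
autoplot.diameter_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Stem diameter (cm)", y = "Density",
                  title = "Kernel density of pilot stem diameters")
}
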