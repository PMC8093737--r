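#' Lognormal sampling parameters for a component
#'
#' A mass predicted on the log scale as `N(mu_log, se_log^2)` is lognormal
#' after back-transformation. To make the lognormal's *mean* equal the
#' back-transformed point estimate `exp(mu_log)` (rather than its median),
#' the meanlog is shifted down by half the variance:
#' `meanlog = mu_log - se_log^2 / 2`, `sdlog = se_log`.
#'
#' @param mu_log,se_log Expected log mass and its prediction standard error
#'   (vectorised; `se_log >= 0`).
#' @return A tibble with columns `meanlog` and `sdlog`.
#' @examples
#' lognormal_params(1, 0.5)  # mean of this lognormal is exp(1)
#' @export
lognormal_params <- function(mu_log, se_log) {
  if (!is.numeric(se_log) || anyNA(se_log) || any(se_log < 0)) {
    abort("`se_log` must be non-negative.")
  }
  tibble::tibble(meanlog = mu_log - se_log^2 / 2, sdlog = se_log)
}

#' Monte-Carlo plot total with 95% interval
#'
#' Propagates per-component prediction error to the plot level: each
#' component is drawn independently from its mean-corrected lognormal
#' (see [lognormal_params()]), draws are summed per replicate, and the
#' empirical `quantiles` of the replicate totals give the interval. The sum
#' of lognormals has no closed-form distribution, hence the Monte-Carlo
#' construction. "Uncertainty" is the range of that interval.
#'
#' Given a seed the result is reproducible and independent of the order of
#' the component rows: components are drawn in a canonical order (sorted by
#' `mu_log`, then `se_log`) from a single stream.
#'
#' @param estimates A tibble with columns `mu_log` and `se_log`, e.g. from
#'   [estimate_components()] or [single_component_estimates()]; at least one
#'   row.
#' @param n_draws Number of Monte-Carlo replicates (>= 100; default 10,000).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param quantiles Lower and upper probabilities of the interval.
#' @return A one-row tibble of class `plot_biomass`: `point_kg` (sum of
#'   component point estimates `exp(mu_log)`), `ci_lwr_kg`, `ci_upr_kg`,
#'   `uncertainty_kg`, `n_draws`, `seed`.
#' @export
mc_plot_total <- function(estimates, n_draws = 10000, seed = NULL,
                          quantiles = c(0.025, 0.975)) {
  check_columns(estimates, c("mu_log", "se_log"), "estimate table")
  if (nrow(estimates) == 0L) abort("At least one component estimate is required.")
  if (n_draws < 100) abort("`n_draws` must be at least 100.")
  if (length(quantiles) != 2L || any(quantiles <= 0) || any(quantiles >= 1) ||
      quantiles[1] >= quantiles[2]) {
    abort("`quantiles` must be two increasing probabilities in (0, 1).")
  }
  ord <- order(estimates$mu_log, estimates$se_log)
  pars <- lognormal_params(estimates$mu_log[ord], estimates$se_log[ord])
  totals <- with_seed(seed, {
    tot <- numeric(n_draws)
    for (i in seq_len(nrow(pars))) {
      tot <- tot + rlnorm(n_draws, meanlog = pars$meanlog[i], sdlog = pars$sdlog[i])
    }
    tot
  })
  ci <- unname(quantile(totals, probs = quantiles))
  out <- tibble::tibble(
    point_kg       = sum(exp(estimates$mu_log)),
    ci_lwr_kg      = ci[1],
    ci_upr_kg      = ci[2],
    uncertainty_kg = ci[2] - ci[1],
    n_draws        = as.integer(n_draws),
    seed           = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  structure(out, class = c("plot_biomass", class(out)))
}

#' Compare single- and two-component plot estimates
#'
#' Runs both estimation pipelines over the same plots: the two-component
#' path converts inventory components (tips + frustra) through the tip and
#' internode models, the single-component path converts each shrub's DRC
#' through the whole-shrub allometry. Each plot-method combination gets its
#' own Monte-Carlo stream derived from `seed`, so the two methods are
#' propagated independently.
#'
#' @param inventory Component tibble with columns `plot_id`, `kind`,
#'   `d1_cm`, `d2_cm`, `length_cm` (see [read_inventory_csv()]).
#' @param drc Tibble with columns `plot_id`, `drc_cm`, one row per shrub.
#'   Every plot in `inventory` must be present.
#' @param tip_fit,internode_fit,whole_fit Fitted models (see
#'   [fit_loglog()], [fit_density_loglog()]).
#' @inheritParams mc_plot_total
#' @return A tibble of class `method_comparison`, one row per plot per
#'   method (`"single"` / `"two_component"`), with the [mc_plot_total()]
#'   columns.
#' @seealso [uncertainty_ratio()]
#' @export
compare_methods <- function(inventory, drc, tip_fit, internode_fit, whole_fit,
                            n_draws = 10000, seed = NULL,
                            quantiles = c(0.025, 0.975)) {
  check_columns(inventory, c("plot_id", "kind", "d1_cm", "d2_cm", "length_cm"),
                "inventory")
  check_columns(drc, c("plot_id", "drc_cm"), "DRC table")
  if (nrow(inventory) == 0L) abort("The plot inventory is empty.")
  plots <- unique(inventory$plot_id)
  missing_drc <- setdiff(plots, unique(drc$plot_id))
  if (length(missing_drc) > 0L) {
    abort(sprintf("No DRC records for plot(s): %s",
                  paste(missing_drc, collapse = ", ")))
  }

  res <- purrr::imap(plots, function(pid, k) {
    inv_p <- dplyr::filter(inventory, .data$plot_id == pid)
    drc_p <- dplyr::filter(drc, .data$plot_id == pid)
    two <- estimate_components(inv_p, tip_fit, internode_fit)
    one <- single_component_estimates(drc_p, whole_fit)
    dplyr::bind_rows(
      dplyr::mutate(
        mc_plot_total(two, n_draws = n_draws, seed = derive_seed(seed, 2 * k),
                      quantiles = quantiles),
        plot_id = pid, method = "two_component", .before = 1L
      ),
      dplyr::mutate(
        mc_plot_total(one, n_draws = n_draws, seed = derive_seed(seed, 2 * k + 1),
                      quantiles = quantiles),
        plot_id = pid, method = "single", .before = 1L
      )
    )
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("method_comparison", setdiff(class(out), "method_comparison")))
}

#' Plot-level uncertainty ratio, single over two-component
#'
#' @param comparison A [compare_methods()] result.
#' @return A tibble with one row per plot: both uncertainties and their
#'   ratio `uncertainty_single / uncertainty_two`. Ratios above 1 mean the
#'   two-component protocol narrowed the plot interval.
#' @export
uncertainty_ratio <- function(comparison) {
  check_columns(comparison, c("plot_id", "method", "uncertainty_kg"),
                "comparison")
  comparison |>
    dplyr::select("plot_id", "method", "uncertainty_kg") |>
    tidyr::pivot_wider(names_from = "method", values_from = "uncertainty_kg",
                       names_prefix = "uncertainty_") |>
    dplyr::mutate(ratio = .data$uncertainty_single / .data$uncertainty_two_component)
}

#' @export
autoplot.method_comparison <- function(object, ...) {
  wide <- uncertainty_ratio(object)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$uncertainty_two_component,
                                     y = .data$uncertainty_single)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Two-component plot uncertainty (kg)",
      y = "Single-component plot uncertainty (kg)",
      title = "Plot-level uncertainty: single vs two-component protocol"
    )
}
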