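# High-level runners binding the pipeline together. These are what the
# command-line script (inst/scripts/shrubmass.R) calls; they are equally
# usable interactively.

#' Fit all calibration models from CSV inputs
#'
#' Reads the destructive calibration tables, fits the tip allometry (aerial
#' tips pooled with whole shrubs of diameter at most `d_max`, exploiting
#' self-similarity), the whole-shrub allometry (all `whole_shrub` rows), and
#' the internode log-log mass-volume model, and optionally writes them as
#' JSON.
#'
#' @param calibration_path CSV of diameter-mass calibration samples (see
#'   [read_calibration_csv()]).
#' @param internodes_path CSV of internode samples (see
#'   [read_internodes_csv()]).
#' @param out_path Optional JSON output path for the fitted models.
#' @param d_max Upper diameter (cm) of the pooled tip fit.
#' @param pool_tips If `TRUE` (default), small whole shrubs are pooled with
#'   aerial tips into the tip fit; if `FALSE` only `aerial_tip` rows are
#'   used.
#' @return A named list of fits: `tip`, `whole`, `internode` (invisibly
#'   written to `out_path` when given).
#' @export
run_fit <- function(calibration_path, internodes_path, out_path = NULL,
                    d_max = 7.5, pool_tips = TRUE) {
  cal <- read_calibration_csv(calibration_path)
  intern <- read_internodes_csv(internodes_path)
  tip_rows <- if (pool_tips) {
    dplyr::filter(cal, .data$role == "aerial_tip" |
                    (.data$role == "whole_shrub" & .data$diameter_cm <= d_max))
  } else {
    dplyr::filter(cal, .data$role == "aerial_tip")
  }
  fits <- list(
    tip = fit_loglog(tip_rows),
    whole = fit_loglog(dplyr::filter(cal, .data$role == "whole_shrub")),
    internode = fit_density_loglog(intern)
  )
  if (!is.null(out_path)) fits_to_json(fits, out_path)
  invisible(fits)
}

#' Estimate plot biomass by both methods
#'
#' Runs [compare_methods()] from file inputs: fitted models (JSON), a plot
#' inventory CSV and a per-shrub DRC CSV, and writes the per-plot,
#' per-method biomass table with Monte-Carlo intervals.
#'
#' @param models_path JSON of fitted models from [run_fit()] (must contain
#'   `tip`, `whole`, `internode`).
#' @param inventory_path Plot inventory CSV.
#' @param drc_path CSV with columns `plot_id`, `shrub_id`, `drc_cm`.
#' @param out_path Optional output CSV path.
#' @param n_draws,seed,quantiles Monte-Carlo settings (see
#'   [mc_plot_total()]).
#' @return The [compare_methods()] tibble (invisibly written to `out_path`
#'   when given).
#' @export
run_estimate <- function(models_path, inventory_path, drc_path,
                         out_path = NULL, n_draws = 10000, seed = NULL,
                         quantiles = c(0.025, 0.975)) {
  fits <- fits_from_json(models_path)
  for (nm in c("tip", "whole", "internode")) {
    if (is.null(fits[[nm]])) {
      abort(sprintf("Model JSON is missing the '%s' fit.", nm))
    }
  }
  inventory <- read_inventory_csv(inventory_path)
  drc <- read_checked_csv(
    drc_path,
    readr::cols(plot_id = readr::col_character(),
                shrub_id = readr::col_character(),
                drc_cm = readr::col_double(),
                .default = readr::col_guess()),
    c("plot_id", "drc_cm"), "DRC table"
  )
  res <- compare_methods(inventory, drc, fits$tip, fits$internode, fits$whole,
                         n_draws = n_draws, seed = seed, quantiles = quantiles)
  if (!is.null(out_path)) readr::write_csv(res, out_path)
  invisible(res)
}

#' Evaluate candidate D_max thresholds from pilot data
#'
#' Runs the sampling-design scan from file inputs: a pilot diameter list and
#' a timing CSV, with the prediction-error allometry either supplied
#' directly (`k`, `p`) or fitted from a models JSON (tip fit's prediction
#' band over `band_range`).
#'
#' @param diameters_path One-column CSV `diameter_cm` of pilot stem
#'   diameters.
#' @param timing_path Timing CSV (see [read_timing_csv()]).
#' @param candidates Candidate `D_max` values (cm).
#' @param k,p Optional prediction-error allometry coefficients; when `NULL`
#'   both are fitted from the `tip` model in `models_path`.
#' @param models_path JSON of fitted models (required when `k`/`p` are not
#'   given).
#' @param band_range Diameter range (cm) of the prediction band used to fit
#'   the PE allometry from the tip model.
#' @param out_path Optional JSON report path.
#' @return The [scan_dmax()] tibble (invisibly written as JSON when
#'   `out_path` is given).
#' @export
run_dmax <- function(diameters_path, timing_path, candidates,
                     k = NULL, p = NULL, models_path = NULL,
                     band_range = c(2.5, 7.5), out_path = NULL) {
  diameters <- read_diameters_csv(diameters_path)$diameter_cm
  timing <- read_timing_csv(timing_path)
  time_fit <- fit_time_cost(timing)
  pe <- if (!is.null(k) && !is.null(p)) {
    pe_model(k, p)
  } else {
    if (is.null(models_path)) {
      abort("Supply either `k` and `p`, or `models_path` with a tip fit.")
    }
    fits <- fits_from_json(models_path)
    if (is.null(fits$tip)) abort("Model JSON is missing the 'tip' fit.")
    fit_pe_model(prediction_band(fits$tip, band_range[1], band_range[2]))
  }
  res <- scan_dmax(diameters, pe, time_fit, candidates)
  if (!is.null(out_path)) {
    jsonlite::write_json(res, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(res)
}

#' Write a full synthetic dataset to disk
#'
#' Generates calibration, internode, inventory, DRC, truth and timing
#' tables with [gen_destructive()], [gen_plot_inventory()] and
#' [gen_timing()], writes them as CSV under `out_dir`, and records the
#' configuration and seed in a `manifest.json` for provenance.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_shrubs Calibration shrubs to dissect.
#' @param n_plots Inventory plots.
#' @param n_timing_plots Timing-study plots.
#' @param seed Integer seed.
#' @return Invisibly, the named vector of file paths written.
#' @export
run_simulate <- function(config = sim_config(), out_dir, n_shrubs = 134,
                         n_plots = 17, n_timing_plots = 14, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- gen_destructive(config, n_shrubs, seed = derive_seed(seed, 1))
  plots <- gen_plot_inventory(config, n_plots, seed = derive_seed(seed, 2))
  timing <- gen_timing(config, n_timing_plots, seed = derive_seed(seed, 3))
  paths <- c(
    calibration = file.path(out_dir, "calibration.csv"),
    internodes = file.path(out_dir, "internodes.csv"),
    inventory = file.path(out_dir, "inventory.csv"),
    drc = file.path(out_dir, "drc.csv"),
    truth = file.path(out_dir, "truth.csv"),
    timing = file.path(out_dir, "timing.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(dest$calibration, paths[["calibration"]])
  readr::write_csv(dest$internodes, paths[["internodes"]])
  readr::write_csv(plots$inventory, paths[["inventory"]])
  readr::write_csv(plots$drc, paths[["drc"]])
  readr::write_csv(plots$truth, paths[["truth"]])
  readr::write_csv(timing, paths[["timing"]])
  manifest <- c(unclass(config),
                list(n_shrubs = n_shrubs, n_plots = n_plots,
                     n_timing_plots = n_timing_plots, seed = seed))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
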