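# CSV readers for the pipeline's tabular interfaces. All files are
# comma-separated, UTF-8, header required, "." decimal.

read_checked_csv <- function(path, col_types, required, what) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  # our own column check below reports missing columns; silence readr's
  # overlapping complaint about unmatched parsers
  data <- withCallingHandlers(
    readr::read_csv(path, col_types = col_types, show_col_types = FALSE),
    warning = function(w) {
      if (grepl("parsers don't match", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  check_columns(data, required, sprintf("%s (%s)", what, path))
  data
}

#' Read pipeline input tables
#'
#' Readers for the four CSV schemas the pipeline consumes. Each checks that
#' the required columns are present and reports the offending file and
#' column by name when they are not.
#'
#' * calibration: `shrub_id, taxon, role (whole_shrub|aerial_tip),
#'   diameter_cm, mass_kg`
#' * internodes: `shrub_id, taxon, d1_cm, d2_cm, length_cm, mass_kg`
#' * inventory: `plot_id, shrub_id, component_seq, kind (tip|frustum),
#'   d1_cm, d2_cm, length_cm` (`d2_cm`/`length_cm` empty for tips)
#' * timing: `plot_id, total_time_s, n_single, n_two`
#' * diameters: single column `diameter_cm`
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_calibration_csv <- function(path) {
  data <- read_checked_csv(
    path,
    readr::cols(shrub_id = readr::col_character(),
                taxon = readr::col_character(),
                role = readr::col_character(),
                diameter_cm = readr::col_double(),
                mass_kg = readr::col_double(),
                .default = readr::col_guess()),
    c("shrub_id", "taxon", "role", "diameter_cm", "mass_kg"),
    "calibration table"
  )
  bad <- setdiff(unique(data$role), c("whole_shrub", "aerial_tip"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown role(s) in calibration table: %s",
                  paste(bad, collapse = ", ")))
  }
  data
}

#' @rdname read_calibration_csv
#' @export
read_internodes_csv <- function(path) {
  read_checked_csv(
    path,
    readr::cols(shrub_id = readr::col_character(),
                taxon = readr::col_character(),
                d1_cm = readr::col_double(), d2_cm = readr::col_double(),
                length_cm = readr::col_double(),
                mass_kg = readr::col_double(),
                .default = readr::col_guess()),
    c("shrub_id", "d1_cm", "d2_cm", "length_cm", "mass_kg"),
    "internode table"
  )
}

#' @rdname read_calibration_csv
#' @export
read_inventory_csv <- function(path) {
  data <- read_checked_csv(
    path,
    readr::cols(plot_id = readr::col_character(),
                shrub_id = readr::col_character(),
                kind = readr::col_character(),
                d1_cm = readr::col_double(), d2_cm = readr::col_double(),
                length_cm = readr::col_double(),
                .default = readr::col_guess()),
    c("plot_id", "shrub_id", "kind", "d1_cm", "d2_cm", "length_cm"),
    "plot inventory"
  )
  bad <- setdiff(unique(data$kind), c("tip", "frustum"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown component kind(s) in inventory: %s",
                  paste(bad, collapse = ", ")))
  }
  data
}

#' @rdname read_calibration_csv
#' @export
read_timing_csv <- function(path) {
  read_checked_csv(
    path,
    readr::cols(plot_id = readr::col_character(),
                total_time_s = readr::col_double(),
                n_single = readr::col_double(), n_two = readr::col_double(),
                .default = readr::col_guess()),
    c("plot_id", "total_time_s", "n_single", "n_two"),
    "timing table"
  )
}

#' @rdname read_calibration_csv
#' @export
read_diameters_csv <- function(path) {
  read_checked_csv(
    path,
    readr::cols(diameter_cm = readr::col_double(),
                .default = readr::col_guess()),
    "diameter_cm", "diameter list"
  )
}

# ---- model JSON round-trip -------------------------------------------------

serializable_fit_fields <- c(
  "form", "intercept", "slope", "residual_scale", "n", "df", "mean_logx",
  "sxx", "r2", "slope_se", "intercept_se", "x_range", "predictor", "response"
)

fit_to_list <- function(fit) {
  out <- fit[intersect(serializable_fit_fields, names(fit))]
  out$class <- class(fit)
  out
}

fit_from_list <- function(x) {
  cls <- unlist(x$class)
  x$class <- NULL
  x <- lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  dbl <- c("intercept", "slope", "residual_scale", "mean_logx", "sxx", "r2",
           "slope_se", "intercept_se", "x_range")
  for (nm in dbl) if (!is.null(x[[nm]])) x[[nm]] <- as.double(x[[nm]])
  for (nm in c("n", "df")) if (!is.null(x[[nm]])) x[[nm]] <- as.integer(x[[nm]])
  structure(x, class = cls)
}

#' Write and read fitted models as JSON
#'
#' Serialises a named list of fitted models (log-log allometries and density
#' fits) to JSON at full double precision, so a round trip through disk
#' preserves every field bit-exactly.
#'
#' @param fits A named list of fit objects (e.g.
#'   `list(tip = ..., whole = ..., internode = ...)`).
#' @param path Output/input JSON path.
#' @return `fits_to_json()` returns `path` invisibly; `fits_from_json()`
#'   returns the named list of fit objects.
#' @export
fits_to_json <- function(fits, path) {
  jsonlite::write_json(lapply(fits, fit_to_list), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname fits_to_json
#' @export
fits_from_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, fit_from_list)
}
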