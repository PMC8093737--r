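#' Stem segments and shrub structures
#'
#' A shrub is represented as a tree of stem segments. Each segment records
#' its base diameter; non-terminal segments additionally record the diameter
#' just below the next node (`top_diameter_cm`), their length, and the child
#' segments above the node. Terminal segments carry neither top diameter nor
#' length. A simulated segment may carry its true component mass for use in
#' coverage and conservation checks.
#'
#' @param base_diameter_cm Diameter at the segment base (cm), > 0.
#' @param top_diameter_cm Diameter just below the upper node swelling (cm),
#'   `NULL` for terminal segments.
#' @param length_cm Internode length (cm), `NULL` for terminal segments.
#' @param children List of child `stem_segment`s above the node.
#' @param true_mass_kg Optional known wet mass of this segment alone (for a
#'   terminal segment, the whole aerial shoot; for an internode, the frustum).
#' @return An object of class `stem_segment`.
#' @export
stem_segment <- function(base_diameter_cm, top_diameter_cm = NULL,
                         length_cm = NULL, children = list(),
                         true_mass_kg = NULL) {
  check_positive(base_diameter_cm, "base_diameter_cm")
  if (!is.null(top_diameter_cm)) check_positive(top_diameter_cm, "top_diameter_cm")
  if (!is.null(length_cm)) check_positive(length_cm, "length_cm")
  if (!all(vapply(children, inherits, logical(1), "stem_segment"))) {
    abort("`children` must be a list of stem_segment objects.")
  }
  structure(
    list(
      base_diameter_cm = base_diameter_cm,
      top_diameter_cm  = top_diameter_cm,
      length_cm        = length_cm,
      children         = children,
      true_mass_kg     = true_mass_kg
    ),
    class = "stem_segment"
  )
}

# Total true mass of a segment subtree (NA if any segment lacks a true mass).
subtree_true_mass <- function(seg) {
  own <- seg$true_mass_kg %||% NA_real_
  if (length(seg$children) == 0L) return(own)
  own + sum(vapply(seg$children, subtree_true_mass, numeric(1)))
}

#' Decompose a shrub into tips and frustra (the field algorithm)
#'
#' Applies the two-component field protocol to a shrub structure:
#'
#' 1. at the root collar, record the diameter `D1`;
#' 2. if `D1 <= d_max`, the whole stem above is one aerial-tip component and
#'    measurement stops;
#' 3. otherwise the internode up to the next node is a conic frustum
#'    (`D1`, `D2`, `L`), and each stem above the node re-enters step 2 with
#'    its own base diameter as the new `D1`;
#' 4. root-collar stems with `D1 < d_min` are below the tall-shrub threshold
#'    and are excluded entirely.
#'
#' Multi-stemmed shrubs are passed as a list of root segments; each stem is
#' processed independently.
#'
#' @param shrub A [stem_segment()] or list of them (one per root-collar stem).
#' @param d_min Minimum root-collar diameter of a tall shrub (cm).
#' @param d_max Threshold diameter: stems at or below it are measured as a
#'   single tip, above it as frustra.
#' @return A tibble with columns `component_seq`, `kind` ("tip"/"frustum"),
#'   `d1_cm`, `d2_cm`, `length_cm`, `true_mass_kg` (`NA` unless the structure
#'   carries true masses; for a tip it is the subtree total).
#' @examples
#' shrub <- stem_segment(12, top_diameter_cm = 6, length_cm = 80,
#'                       children = list(stem_segment(5), stem_segment(4)))
#' decompose(shrub, d_min = 2.5, d_max = 7.5)
#' @export
decompose <- function(shrub, d_min = 2.5, d_max = 7.5) {
  if (inherits(shrub, "stem_segment")) shrub <- list(shrub)
  if (!is.list(shrub) ||
      !all(vapply(shrub, inherits, logical(1), "stem_segment"))) {
    abort("`shrub` must be a stem_segment or a list of stem_segments.")
  }
  if (!(d_min <= d_max)) abort("`d_min` must not exceed `d_max`.")

  rows <- list()
  walk_segment <- function(seg) {
    d1 <- seg$base_diameter_cm
    if (d1 <= d_max) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        kind = "tip", d1_cm = d1, d2_cm = NA_real_, length_cm = NA_real_,
        true_mass_kg = subtree_true_mass(seg)
      )
      return(invisible(NULL))
    }
    if (is.null(seg$top_diameter_cm) || is.null(seg$length_cm)) {
      abort(sprintf(
        "Segment with base diameter %.2f cm exceeds d_max = %.2f cm but lacks a top diameter or length.",
        d1, d_max
      ))
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      kind = "frustum", d1_cm = d1, d2_cm = seg$top_diameter_cm,
      length_cm = seg$length_cm,
      true_mass_kg = seg$true_mass_kg %||% NA_real_
    )
    for (child in seg$children) walk_segment(child)
    invisible(NULL)
  }

  for (stem in shrub) {
    if (stem$base_diameter_cm < d_min) next  # below tall-shrub size
    walk_segment(stem)
  }
  out <- if (length(rows) == 0L) {
    tibble::tibble(kind = character(), d1_cm = numeric(), d2_cm = numeric(),
                   length_cm = numeric(), true_mass_kg = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  dplyr::mutate(out, component_seq = dplyr::row_number(), .before = 1L)
}

#' Per-component log-mass predictive distributions
#'
#' Converts measured components into the `(mu_log, se_log)` pairs that feed
#' the Monte-Carlo propagation: tips through the tip allometry at their basal
#' diameter, frustra through the internode log-log mass-volume model at their
#' frustum volume (litres). `se_log` is the full prediction standard error
#' (residual scale combined with estimation error). Tips whose diameter lies
#' outside the calibration range trigger a single extrapolation warning.
#'
#' @param components A component tibble as returned by [decompose()] or
#'   [read_inventory_csv()] (columns `kind`, `d1_cm`, `d2_cm`, `length_cm`).
#' @param tip_fit A [loglog_fit][fit_loglog()] for aerial tips.
#' @param internode_fit A log-log [density fit][fit_density_loglog()].
#' @return `components` with columns `mu_log`, `se_log`, `point_kg` appended.
#' @export
estimate_components <- function(components, tip_fit, internode_fit) {
  check_columns(components, c("kind", "d1_cm", "d2_cm", "length_cm"),
                "component table")
  if (!inherits(tip_fit, "loglog_fit")) abort("`tip_fit` must be a loglog_fit.")
  if (!inherits(internode_fit, "loglog_fit")) {
    abort("`internode_fit` must be a log-log density fit.")
  }
  if (nrow(components) == 0L) {
    return(dplyr::mutate(components, mu_log = numeric(0), se_log = numeric(0),
                         point_kg = numeric(0)))
  }
  if (!all(components$kind %in% c("tip", "frustum"))) {
    abort("Component `kind` must be 'tip' or 'frustum'.")
  }
  mu <- se <- rep(NA_real_, nrow(components))

  is_tip <- components$kind == "tip"
  if (any(is_tip)) {
    d <- components$d1_cm[is_tip]
    n_out <- sum(d < tip_fit$x_range[1] | d > tip_fit$x_range[2])
    if (n_out > 0L) {
      warn(sprintf(
        "%d tip diameter(s) fall outside the tip calibration range [%.2f, %.2f] cm; predictions are extrapolations.",
        n_out, tip_fit$x_range[1], tip_fit$x_range[2]
      ))
    }
    p <- predict_log(tip_fit, d)
    mu[is_tip] <- p$mu_log
    se[is_tip] <- p$se_pred
  }
  if (any(!is_tip)) {
    f <- components[!is_tip, ]
    v_L <- frustum_volume(f$d1_cm, f$d2_cm, f$length_cm) / 1000
    p <- predict_log(internode_fit, v_L)
    mu[!is_tip] <- p$mu_log
    se[!is_tip] <- p$se_pred
  }
  dplyr::mutate(components, mu_log = mu, se_log = se, point_kg = exp(mu))
}

#' Single-component (DRC-only) estimates
#'
#' One predictive distribution per shrub from its diameter at root collar
#' alone, regardless of size — the conventional one-measurement protocol the
#' two-component method is compared against.
#'
#' @param drc A numeric vector of root-collar diameters (cm), or a data frame
#'   with a `drc_cm` column (extra columns such as ids are carried through).
#' @param whole_fit A whole-shrub [loglog_fit][fit_loglog()].
#' @return A tibble with one row per shrub: input columns plus `mu_log`,
#'   `se_log`, `point_kg`.
#' @export
single_component_estimates <- function(drc, whole_fit) {
  if (!inherits(whole_fit, "loglog_fit")) abort("`whole_fit` must be a loglog_fit.")
  if (is.numeric(drc)) drc <- tibble::tibble(drc_cm = drc)
  check_columns(drc, "drc_cm", "DRC table")
  check_positive(drc$drc_cm, "drc_cm")
  p <- predict_log(whole_fit, drc$drc_cm)
  dplyr::mutate(tibble::as_tibble(drc),
                mu_log = p$mu_log, se_log = p$se_pred, point_kg = exp(p$mu_log))
}
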