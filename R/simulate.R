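#' Configuration of the synthetic-shrub generator
#'
#' Bundles the generative assumptions the estimation method relies on:
#' tip masses follow the power law `tip_a * D^tip_b` with multiplicative
#' lognormal noise, internode masses are wet density times frustum volume
#' with lognormal noise, shrub architecture is a self-similar branching tree
#' whose child stems approximately conserve cross-sectional area at nodes,
#' and root-collar diameters are lognormal (truncated at `d_min`).
#'
#' Defaults follow the reported calibration for Alaskan alder/willow tall
#' shrubs: combined tip allometry `M = 0.07 * D^2.437`, wet density
#' 0.9 kg/L, thresholds `d_min` 2.5 cm and `d_max` 7.5 cm, plot densities of
#' ~84 tall shrubs per 169 m^2 plot, and timing coefficients t0 = 300 s,
#' t1 = 26 s, t2 = 111 s with residual sd 543 s over ~92 single- and ~6
#' two-component measures per plot. The DRC distribution (meanlog log 5,
#' sdlog 0.5) puts about 8% of stems above 10 cm, matching pilot conditions.
#' Noise scales not reported anywhere default to `tip_sdlog = 0.45` and
#' `internode_sdlog = 0.15`.
#'
#' @param tip_a,tip_b True tip allometry coefficients.
#' @param tip_sdlog Lognormal residual sd of tip mass (log scale).
#' @param density_kg_L True wet wood density.
#' @param internode_sdlog Lognormal residual sd of internode mass.
#' @param taper_rate Fractional diameter decrease per cm of internode length.
#' @param internode_length_meanlog,internode_length_sdlog Lognormal
#'   parameters of internode lengths (cm).
#' @param branch_probs Probabilities of 1, 2, 3 child stems at a node.
#' @param branch_jitter_sdlog Lognormal jitter on the area-preserving
#'   child-diameter split.
#' @param drc_meanlog,drc_sdlog Lognormal parameters of root-collar
#'   diameters (truncated below at `d_min`).
#' @param d_min,d_max Tall-shrub minimum and tip/frustum threshold (cm).
#' @param plot_shrub_mean Poisson mean number of tall shrubs per plot.
#' @param t0_s,t1_s,t2_s,time_sigma_s Timing-model coefficients (seconds).
#' @param n_single_mean,n_two_mean Mean per-plot measurement counts in the
#'   timing study.
#' @param count_sdlog Lognormal sd of the plot-to-plot variation in expected
#'   measurement counts (counts are Poisson mixed over a lognormal mean,
#'   i.e. overdispersed, as real plots are: some plots are nearly empty,
#'   others dense).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tip_a = 0.07, tip_b = 2.437, tip_sdlog = 0.45,
                       density_kg_L = 0.9, internode_sdlog = 0.15,
                       taper_rate = 0.003,
                       internode_length_meanlog = log(60),
                       internode_length_sdlog = 0.35,
                       branch_probs = c(0.35, 0.45, 0.20),
                       branch_jitter_sdlog = 0.10,
                       drc_meanlog = log(5), drc_sdlog = 0.5,
                       d_min = 2.5, d_max = 7.5,
                       plot_shrub_mean = 84,
                       t0_s = 300, t1_s = 26, t2_s = 111, time_sigma_s = 543,
                       n_single_mean = 92, n_two_mean = 6,
                       count_sdlog = 0.9) {
  for (nm in c("tip_a", "tip_b", "density_kg_L", "d_min", "d_max",
               "plot_shrub_mean", "t0_s", "t1_s", "t2_s",
               "n_single_mean", "n_two_mean")) {
    check_positive(get(nm), nm)
  }
  for (nm in c("tip_sdlog", "internode_sdlog", "taper_rate",
               "branch_jitter_sdlog", "time_sigma_s", "count_sdlog")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a non-negative number.", nm))
    }
  }
  if (!(d_min < d_max)) abort("`d_min` must be less than `d_max`.")
  if (length(branch_probs) != 3L || any(branch_probs < 0) ||
      sum(branch_probs) <= 0) {
    abort("`branch_probs` must be 3 non-negative weights.")
  }
  structure(as.list(environment())[c(
    "tip_a", "tip_b", "tip_sdlog", "density_kg_L", "internode_sdlog",
    "taper_rate", "internode_length_meanlog", "internode_length_sdlog",
    "branch_probs", "branch_jitter_sdlog", "drc_meanlog", "drc_sdlog",
    "d_min", "d_max", "plot_shrub_mean", "t0_s", "t1_s", "t2_s",
    "time_sigma_s", "n_single_mean", "n_two_mean", "count_sdlog"
  )], class = "sim_config")
}

draw_drc <- function(config) {
  # lognormal truncated below at d_min so every generated shrub is "tall"
  repeat {
    d <- rlnorm(1, config$drc_meanlog, config$drc_sdlog)
    if (d >= config$d_min) return(d)
  }
}

#' Generate one synthetic shrub
#'
#' Builds a branching stem structure recursively. A stem with base diameter
#' at or below `d_max` becomes a terminal aerial tip whose true mass is
#' `tip_a * D^tip_b * exp(N(0, tip_sdlog^2))`. A larger stem becomes an
#' internode: its length is lognormal, its top diameter tapers with length,
#' its true mass is `density * V(frustum) * exp(N(0, internode_sdlog^2))`,
#' and the node spawns 1-3 children whose squared diameters sum to
#' approximately the pre-node squared diameter (area-preserving split with
#' lognormal jitter) — the architectural self-similarity the tip allometry
#' exploits.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param drc Optional fixed root-collar diameter (cm); drawn from the
#'   configured lognormal when `NULL`.
#' @return A [stem_segment()] with `true_mass_kg` attached throughout.
#' @export
gen_shrub <- function(config, seed = NULL, drc = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    d0 <- drc %||% draw_drc(config)
    build_segment(config, d0, depth = 1L)
  })
}

build_segment <- function(config, d, depth) {
  if (depth > 60L) {
    abort("Runaway shrub recursion; check taper and branching settings.")
  }
  if (d <= config$d_max) {
    mass <- config$tip_a * d^config$tip_b *
      exp(rnorm(1, 0, config$tip_sdlog))
    return(stem_segment(d, true_mass_kg = mass))
  }
  len <- rlnorm(1, config$internode_length_meanlog, config$internode_length_sdlog)
  d2 <- max(d * (1 - config$taper_rate * len), 0.4 * d)
  vol_L <- frustum_volume(d, d2, len) / 1000
  mass <- config$density_kg_L * vol_L * exp(rnorm(1, 0, config$internode_sdlog))
  n_child <- sample.int(3L, 1L, prob = config$branch_probs)
  shares <- rgamma(n_child, shape = 4, rate = 1)
  shares <- shares / sum(shares)
  child_d <- pmin(d2 * sqrt(shares) *
                    exp(rnorm(n_child, 0, config$branch_jitter_sdlog)),
                  0.98 * d2)
  child_d <- child_d[child_d >= 0.3]
  children <- lapply(child_d, function(cd) build_segment(config, cd, depth + 1L))
  stem_segment(d, top_diameter_cm = d2, length_cm = len,
               children = children, true_mass_kg = mass)
}

#' Generate destructive calibration datasets
#'
#' Dissects `n_shrubs` generated shrubs into the two calibration tables the
#' fitting functions consume: whole-shrub/tip diameter-mass pairs, and
#' internode (D1, D2, L, mass) tuples. Every shrub contributes a
#' `whole_shrub` row (DRC and total true mass); shrubs larger than `d_max`
#' additionally contribute their aerial tips (role `aerial_tip`) and their
#' internodes.
#'
#' @inheritParams gen_shrub
#' @param n_shrubs Number of shrubs to dissect (>= 3).
#' @param taxa Taxon labels sampled per shrub.
#' @return A list with tibbles `calibration` (`shrub_id`, `taxon`, `role`,
#'   `diameter_cm`, `mass_kg`) and `internodes` (`shrub_id`, `taxon`,
#'   `d1_cm`, `d2_cm`, `length_cm`, `mass_kg`).
#' @export
gen_destructive <- function(config, n_shrubs, seed = NULL,
                            taxa = c("Alnus viridis", "Alnus incana", "Salix sp.")) {
  stopifnot(inherits(config, "sim_config"))
  if (n_shrubs < 3L) abort("At least 3 shrubs are required for calibration.")
  with_seed(seed, {
    cal <- list()
    intern <- list()
    for (i in seq_len(n_shrubs)) {
      id <- sprintf("S%04d", i)
      taxon <- sample(taxa, 1L)
      shrub <- gen_shrub(config)
      comps <- decompose(shrub, d_min = config$d_min, d_max = config$d_max)
      cal[[length(cal) + 1L]] <- tibble::tibble(
        shrub_id = id, taxon = taxon, role = "whole_shrub",
        diameter_cm = shrub$base_diameter_cm,
        mass_kg = sum(comps$true_mass_kg)
      )
      tips <- dplyr::filter(comps, .data$kind == "tip")
      frus <- dplyr::filter(comps, .data$kind == "frustum")
      if (nrow(frus) > 0L) {  # a dissected large shrub: harvest parts too
        cal[[length(cal) + 1L]] <- tibble::tibble(
          shrub_id = id, taxon = taxon, role = "aerial_tip",
          diameter_cm = tips$d1_cm, mass_kg = tips$true_mass_kg
        )
        intern[[length(intern) + 1L]] <- tibble::tibble(
          shrub_id = id, taxon = taxon,
          d1_cm = frus$d1_cm, d2_cm = frus$d2_cm,
          length_cm = frus$length_cm, mass_kg = frus$true_mass_kg
        )
      }
    }
    list(
      calibration = dplyr::bind_rows(cal),
      internodes = if (length(intern) > 0L) dplyr::bind_rows(intern) else
        tibble::tibble(shrub_id = character(), taxon = character(),
                       d1_cm = numeric(), d2_cm = numeric(),
                       length_cm = numeric(), mass_kg = numeric())
    )
  })
}

#' Generate plot inventories with known true totals
#'
#' Simulates field plots: shrub counts are Poisson, each shrub is generated
#' and decomposed at the configured thresholds, and the true plot biomass is
#' the sum of the attached true component masses — the ground truth for
#' end-to-end coverage checks of the Monte-Carlo plot intervals.
#'
#' @inheritParams gen_shrub
#' @param n_plots Number of plots.
#' @param shrubs_per_plot Optional fixed shrub count per plot (overrides the
#'   Poisson draw with mean `config$plot_shrub_mean`).
#' @return A list with tibbles `inventory` (`plot_id`, `shrub_id`,
#'   `component_seq`, `kind`, `d1_cm`, `d2_cm`, `length_cm`), `drc`
#'   (`plot_id`, `shrub_id`, `drc_cm`) and `truth` (`plot_id`,
#'   `true_total_kg`).
#' @export
gen_plot_inventory <- function(config, n_plots, seed = NULL,
                               shrubs_per_plot = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_positive(n_plots, "n_plots")
  with_seed(seed, {
    inv <- list(); drc <- list(); truth <- list()
    for (p in seq_len(n_plots)) {
      pid <- sprintf("P%03d", p)
      n_shrubs <- shrubs_per_plot %||% rpois(1, config$plot_shrub_mean)
      total <- 0
      for (s in seq_len(n_shrubs)) {
        sid <- sprintf("%s-S%03d", pid, s)
        shrub <- gen_shrub(config)
        comps <- decompose(shrub, d_min = config$d_min, d_max = config$d_max)
        total <- total + sum(comps$true_mass_kg)
        inv[[length(inv) + 1L]] <- dplyr::mutate(
          dplyr::select(comps, -"true_mass_kg"),
          plot_id = pid, shrub_id = sid, .before = 1L
        )
        drc[[length(drc) + 1L]] <- tibble::tibble(
          plot_id = pid, shrub_id = sid, drc_cm = shrub$base_diameter_cm
        )
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        plot_id = pid, true_total_kg = total
      )
    }
    empty_inv <- tibble::tibble(
      plot_id = character(), shrub_id = character(),
      component_seq = integer(), kind = character(),
      d1_cm = numeric(), d2_cm = numeric(), length_cm = numeric()
    )
    list(
      inventory = if (length(inv) > 0L) dplyr::bind_rows(inv) else empty_inv,
      drc = if (length(drc) > 0L) dplyr::bind_rows(drc) else
        tibble::tibble(plot_id = character(), shrub_id = character(),
                       drc_cm = numeric()),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Generate a pilot timing study
#'
#' Per-plot total time is `t0 + t1 * n_single + t2 * n_two + N(0, sigma^2)`
#' (truncated just above zero), with Poisson measurement counts.
#'
#' @inheritParams gen_plot_inventory
#' @return A tibble with columns `plot_id`, `total_time_s`, `n_single`,
#'   `n_two`.
#' @export
gen_timing <- function(config, n_plots, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_positive(n_plots, "n_plots")
  with_seed(seed, {
    s <- config$count_sdlog
    n1 <- rpois(n_plots, rlnorm(n_plots, log(config$n_single_mean) - s^2 / 2, s))
    n2 <- rpois(n_plots, rlnorm(n_plots, log(config$n_two_mean) - s^2 / 2, s))
    t <- config$t0_s + config$t1_s * n1 + config$t2_s * n2 +
      rnorm(n_plots, 0, config$time_sigma_s)
    tibble::tibble(
      plot_id = sprintf("T%03d", seq_len(n_plots)),
      total_time_s = pmax(t, 1),
      n_single = n1, n_two = n2
    )
  })
}
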