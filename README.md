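# shrubmass

Precise plot-level biomass estimates for tall shrubs (diameter at root
collar, DRC, ≥ 2.5 cm) from stem diameters — for field ecologists and
carbon-accounting crews who calibrate their own allometries and need
defensible uncertainty at the plot level.

## The method

Power-function allometry `M = a·D^b`, fitted as
`ln M = b·ln D + ln a + ε` with `ε ~ N(0, σ²)`, predicts individual
wet field-mass with an error whose back-transformed 95% prediction
interval widens roughly as `D^2.4`. Plot totals are therefore dominated by
the uncertainty of the few largest shrubs. `shrubmass` implements a
two-component protocol that caps this growth:

* **Aerial tips** (terminal shoots with basal diameter ≤ a threshold
  `D_max`) are predicted from the tip allometry — legitimately shared with
  whole small shrubs, because shrub architecture is self-similar
  (`band_overlap()` quantifies this with prediction-band overlap).
* **Internodes** (stem sections with `D > D_max`) are measured as conic
  frusta, `V = πL(D₁² + D₁D₂ + D₂²)/12`, and converted to mass by wet wood
  density calibrated with `fit_density_loglog()`.
* **Propagation**: every component's log-scale prediction error is sampled
  from a mean-corrected lognormal (`meanlog = μ − se²/2`) and summed by
  Monte Carlo (`mc_plot_total()`, 10,000 draws) into a plot-level point
  estimate with empirical 95% bounds; "uncertainty" is the interval range.
* **Design**: `scan_dmax()` picks the threshold by the benefit/cost rule
  `E[PE₁]/E[PE₂] ≥ (t₂·P(D > D_max) + t₁)/t₁`, integrating the
  prediction-error allometry `PE = k·D^p` against a kernel density of
  pilot stem diameters and a timing regression
  `time = t₀ + t₁·n_single + t₂·n_two`.

A seeded simulator (`sim_config()`, `gen_shrub()`, `gen_plot_inventory()`,
…) generates branching shrubs with known true masses under exactly the
assumptions above, so the whole pipeline is testable end to end without
any field data.

## Worked example

Calibrate from a (here: simulated) destructive sample, estimate three
plots both ways, and scan thresholds:

```r
library(shrubmass)
library(dplyr)

cfg  <- sim_config()                           # study-scale generative world
dest <- gen_destructive(cfg, 134, seed = 20)   # dissected calibration shrubs

tip_fit   <- fit_loglog(filter(dest$calibration,
               role == "aerial_tip" |
               (role == "whole_shrub" & diameter_cm <= 7.5)))
whole_fit <- fit_loglog(filter(dest$calibration, role == "whole_shrub"))
int_fit   <- fit_density_loglog(dest$internodes)
tip_fit
#> Log-log power-function fit: mass_kg = 0.08173 * diameter_cm^2.356
#>   n = 190, residual scale = 0.4014, R^2 = 0.759

density_ci(int_fit)          # wet density with 95% CI, kg/L
#>   density_kg_L ci_lwr_kg_L ci_upr_kg_L level
#> 1        0.976       0.884        1.08  0.95

plots <- gen_plot_inventory(cfg, 3, seed = 21, shrubs_per_plot = 12)
cmp <- compare_methods(plots$inventory, plots$drc,
                       tip_fit, int_fit, whole_fit,
                       n_draws = 10000, seed = 22)
uncertainty_ratio(cmp)
#>   plot_id uncertainty_two_component uncertainty_single ratio
#> 1    P001                      29.1               38.2  1.31
#> 2    P002                      29.4               29.8  1.02
#> 3    P003                      37.6               59.9  1.59
```

The ratio column is the plot-level 95%-interval range of the conventional
single-measurement protocol over that of the two-component protocol:
plots P001 and P003 contain large shrubs, and measuring them as frusta
narrows their intervals by 24–37%; P002 happens to hold only small shrubs,
so the methods tie. Threshold choice from the same pilot data:

```r
pe <- fit_pe_model(prediction_band(tip_fit, 2.5, 7.5))
tc <- fit_time_cost(gen_timing(cfg, 14, seed = 23))
scan_dmax(plots$drc$drc_cm, pe, tc, candidates = c(5, 7.5, 10))
#>   d_max_cm epe1_kg epe2_kg pe_ratio p_exceed e_t2_s time_ratio acceptable
#> 1      5.0    14.6    1.02    14.35   0.6667  79.37       3.99       TRUE
#> 2      7.5    14.6    5.24     2.79   0.2500  29.76       2.12       TRUE
#> 3     10.0    14.6    9.73     1.50   0.0833   9.92       1.37       TRUE
```

Every candidate passes (`pe_ratio ≥ time_ratio`), so the smallest
convenient threshold buys the most precision; at `D_max = 10` cm the
two-component measure costs 1.37× the time of a single measure and returns
1.50× the precision.

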