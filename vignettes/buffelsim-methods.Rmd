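---
title: "Modeling buffelgrass invasion and the grass-fire cycle with buffelsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling buffelgrass invasion and the grass-fire cycle with buffelsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buffelsim)
```

## The problem

Buffelgrass (*Cenchrus ciliaris*) is a perennial African grass invading the
Sonoran Desert. It spreads by seed, thickens within established patches
("patch infill"), and — critically — carries fire through a desert flora
that is not fire adapted. Dense buffelgrass burns, burning converts native
desert to buffelgrass savanna, and savanna carries more fire: the grass-fire
cycle. Managers need forecasts of how much landscape could be invaded and
burned over decades, and those forecasts depend on parameters that are
genuinely uncertain (how fast patches infill, how often monsoon seasons are
wet, how much wet years accelerate infill, how much of the landscape is
susceptible at all).

`buffelsim` is a state-and-transition simulation model (STSM) of this
system, together with the uncertainty experiment around it: factorial
scenario sets over initialization and ecological parameter levels, Monte
Carlo ensembles, and variance attribution (ANOVA and hierarchical
partitioning) to rank which uncertainties matter.

## The landscape

The landscape is a row-major grid of 0.25-ha cells (a 50 m cell on an
arbitrary local grid; exported rasters carry no coordinate reference
system). Each cell belongs to one stratum:

* **susceptible desert** — desert predicted suitable for buffelgrass;
* **unsusceptible desert** — desert below the suitability threshold;
* **grassland ecotone** — the strip between desert and forest (invadable by
  default; this is a configurable assumption, not an asserted fact);
* **excluded** — high-elevation forest, outside the simulated area. Cells
  adjacent (8-neighbor) to it are flagged as the *forest edge*, used to
  count fires that reach the forest.

Because the real habitat-suitability raster and survey maps are not
shipped, a synthetic landscape module emulates their statistical structure:

1. `generate_suitability_surface()` smooths Gaussian white noise with a
   Gaussian kernel (FFT convolution; `correlation_length` is the kernel
   standard deviation in cells, default 15) and maps the standardized field
   through the normal CDF, giving values in [0, 1] with tunable spatial
   autocorrelation.
2. `calibrate_thresholds()` applies a rank-preserving piecewise-linear
   transform so that the desert area at or above each susceptibility
   threshold (0.55 / 0.50 / 0.45 for the low / moderate / high levels)
   matches its target area — by default 9,735 / 10,845 / 12,013 ha on a
   20,000-ha desert (80,000 cells). Targets scale proportionally when a
   smaller grid is configured.
3. `assign_initial_cover()` places the initial cover-class areas (defaults
   178.8 / 818.3 / 503 / 121.8 ha at the moderate initial-condition
   level) as clustered patches: seeds drawn with
   probability proportional to suitability, grown by 8-neighbor accretion.
   Clustering is deliberate — real infestations are patchy, and patchiness
   controls fire connectivity. Targets are rounded to whole cells, so
   assigned area is within 0.25 ha of target.

The default extent (a 210 x 400 grid: 200 desert rows, a 5-row ecotone, a
5-row excluded forest block) is a design choice: real park
extents mix simulated desert with excluded forest, so we use a desert comfortably larger than the largest
susceptible target. Everything is configurable.

## State classes and the annual update

Each cell is in one of seven classes: `uninvaded`, `seedbank`, cover bins
`<1%`, `1-10%`, `>10-50%`, `>50%`, and `converted` (post-fire buffelgrass
savanna, absorbing). One time step is one year, applied in this order:

1. **Seed dispersal.** Every occupied cell seeds each uninvaded cell within
   a radius-1 Moore kernel independently, with per-source-class annual
   probabilities (defaults 0.01 / 0.05 / 0.15 / 0.30 by increasing cover;
   `converted` disperses like `>50%`). A target becomes `seedbank` if any
   trial succeeds. The kernel and probabilities are the simplest choice
   that yields contiguous spread; the radius is configurable.
2. **Seedbank dynamics.** Cells that were seedbank at the start of the
   step first attempt establishment to `<1%` cover (probability 0.2,
   invadable strata only), otherwise die back to uninvaded with probability
   0.1, otherwise persist. Seed arriving this year cannot establish this
   year. Unsusceptible desert may hold seedbank (mortality only) by
   default; both probabilities and the flag are configurable, and the
   defaults keep the seedbank a transient pool.
3. **Aging and patch infill.** Cells that were in a cover class at the
   start of the step age by `age_increment(n, is_wet)` years: 1 in a dry
   year, `n` in a wet year (the default year plus `n - 1` additional
   years), where `n` is the wet-year infill acceleration divisor (2 / 3 / 4
   for slow / moderate / fast). A cell whose age reaches its class's
   time-in-class advances exactly one class and resets its age to 0, even
   if the increment overshot; `>50%` and `converted` never advance.

Time-in-class values are expert-elicited quantities for which no public
figures exist. The defaults here — 12 / 8 / 5 years per class
for the low / moderate / high infill-rate levels — are working assumptions
on the scale of one to a few decades per class, clearly flagged as such in
the configuration. Every structural property of the simulator (area
conservation, monotone invasion, dominance orderings) holds for any values,
and the test suite asserts them as properties rather than at particular
parameter points.

### Random numbers and couplings

Each step draws three full-grid uniform matrices (dispersal,
establishment, mortality) in a fixed order, and child seeds are derived by
a stable hash of (master seed, process, realization, year) — not of the
scenario. Two consequences, both load-bearing:

* runs are bit-reproducible from the master seed;
* scenarios sharing a master seed are coupled by common random numbers, so
  dominance relations hold realization by realization: faster infill ≥
  slower, a wet-year schedule that is a superset of another ≥ the other,
  and wet-fast ≥ moderate ≥ dry-slow at every time step. Wet-year
  schedules are drawn as `u < p` against shared uniforms, so a higher
  wet-year probability wets a superset of years.

## Climate

A year is "wet" when both monsoon length and cumulative monsoon
precipitation exceed their baseline medians; `estimate_wet_probability()`
implements that definition ("above median" is read strictly, so a year
tied with a median counts as not wet) on a CSV of monsoon records. The three probability levels used by the scenarios, 0.10 /
0.267 / 0.57, are configuration constants from a median-exceedance analysis of the Tucson
International Airport monsoon record, not recomputed: the station record
itself is external data. `sample_wet_years()` draws schedules in `variable` mode (independent
per realization) or `constant` mode (one schedule shared across
realizations, the design used when fire is on).

## Fire

Full fire-area simulators such as FARSITE — with their weather, wind and
topography inputs and file formats — are out of scope here. `buffelsim`
instead uses a documented stochastic
contagion surrogate that preserves the mechanism that matters for the
grass-fire cycle — fire size grows with contiguous high-cover area:

* one ignition per year, uniform over all simulated cells; an ignition on
  non-flammable fuel burns nothing;
* only `>10-50%`, `>50%`, and `converted` carry fire (more than 10% cover
  is required), with spread weights 0.6 / 1.0 / 1.0;
* each burning cell attempts each 8-neighbor once with probability
  `spread_prob x weight` (default `spread_prob` 0.35, a surrogate tuning
  knob, never a result), and the front grows until no new cells ignite.
  With success probability 1 the burn is exactly the connected flammable
  component — the flood-fill oracle the tests check against.

Fire effects: burned `>50%` becomes `converted` (age 0); `converted` stays
converted. The effect of fire on `>10-50%` cells is not a settled ecological
fact, so the default is "no class change", with `reset_age` and
`promote` exposed as alternatives for sensitivity exploration rather than
inventing a promotion rate. Burn metrics per run: years with fire (burned
area > 0), cumulative burned area (re-burns counted every year), landscape
burned area (union of ever-burned cells), and fires reaching the forest
edge (burned set contains a forest-edge cell).

## Scenarios and the ensemble

`build_initialization_scenarios()` crosses susceptibility x initial
conditions (9 scenarios); `build_ecological_scenarios()` crosses infill
rate x wet-year probability x acceleration (27); `build_fire_scenarios()`
is the three-preset fire subset (dry-slow, moderate, wet-fast) with
constant wet-year timing, reflecting the computational cost of simulating
fire at every time step.
`run_ensemble()` runs 20 realizations of 30 years by default, recording
per-year state-class areas, the midpoint-weighted invaded area
(weights 0.005 / 0.055 / 0.3 / 0.75 / 1.0), and burned area. Whether the
landscape is regenerated per realization (default) or shared
(`share_landscape = TRUE`) is a flag; either convention is defensible.

## Variance attribution

End-of-run invaded area is attributed to design factors two ways:

* `anova_decomposition()` — `stats::aov` with interactions; the scenario
  designs are balanced, so sequential sums of squares are order-free.
* `hierarchical_partition()` — the independent contribution of each factor
  is the average R² increment from adding it, over all orderings of the
  factors, computed by subset enumeration with factorial weights (at most
  8 predictors; R² of a least-squares fit on factor encodings is the
  goodness of fit, matching the regression variant of the method). The
  independent contributions sum exactly to the full-model R², and the test
  suite checks the implementation against an explicit all-orderings
  enumeration.

Absolute attribution percentages depend on the elicited infill times,
which are working assumptions here, so they are not fixed reference
values; what the package asserts is the qualitative structure — on an experiment
where one factor drives the response, that factor receives the dominant
share.

## What the synthetic landscape does and does not show

The generator reproduces the *statistical* structure the analysis assumes:
calibrated susceptible-area totals, initialization-table cover areas,
spatial autocorrelation, clustered infestations, strata adjacency. It does
not reproduce the park's actual geography — real terrain anisotropy,
roads and washes that channel both spread and fire, or the true
detection-probability model behind the survey maps. Passing tests
therefore demonstrate correctness of the mechanisms and orderings, not
calibrated hectare forecasts for the real park; headline hectare outcomes
additionally depend on the assumed infill times and on the fire surrogate
standing in for a full fire-behavior model.

## Numerical and degenerate-input choices

* Calibration anchors are midpoints between adjacent order statistics, so
  threshold counts are exact on continuous surfaces; saturated targets
  (whole desert susceptible) are handled by anchoring below the minimum.
* `correlation_length = 0` skips smoothing entirely (i.i.d. cells).
* Cover targets round to whole cells (0.25-ha fidelity per class).
* At most one cover-class advance per cell per year; age resets on
  transition regardless of overshoot.
* An all-uninvaded landscape is a fixed point of the annual step; an empty
  burned set is a no-op for fire effects.
* Simulation sizes used in the shipped tests are scaled to desk scale
  (grids from 1 x 1 to 210 x 400; the stochasticity comparison runs a
  100 x 100 grid, 20 realizations, 30 years per timing mode), chosen so the
  full property suite exercises every mechanism in seconds to minutes.

## Limitations

* The fire surrogate has no weather, wind, topography, crown fire or
  spotting; its spread probability is a tuning constant.
* Management transitions (detection, treatment, herbicide) are outside the
  model by design.
* Cover is class-valued, not continuous; "infill" is time-in-class, not a
  growth curve.
* Default time-in-class values are assumptions, not elicited data; absolute
  invaded-area forecasts should be read accordingly.
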