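# buffelsim

Simulation of buffelgrass (*Cenchrus ciliaris*) invasion and the grass-fire
cycle on a gridded Sonoran Desert landscape, for ecologists and land
managers who need to know which model uncertainties actually drive
30-year invasion forecasts.

`buffelsim` is a state-and-transition simulation model (STSM): 0.25-ha
cells hold one of seven state classes — uninvaded, seedbank, buffelgrass
cover `<1%`, `1–10%`, `>10–50%`, `>50%`, and converted savanna — and change
once per year through

* **seed dispersal** into a Moore neighborhood with per-source-class
  probabilities (converted savanna disperses like `>50%` cover),
* **seedbank establishment and mortality**, and
* **age-deterministic patch infill**: a cell advances one cover class when
  its class age reaches the time-in-class *T_c*, where wet monsoon years
  add *n* years of age instead of 1 (acceleration divisor *n* ∈ {2, 3, 4}),

plus an optional cellular fire surrogate: one uniform ignition per year,
spread gated on fuel (more than 10% cover is required to carry fire), and
burned `>50%` cells converting to savanna — the positive feedback of the
grass-fire cycle.

The headline statistic is the midpoint-weighted invaded area

    A_inv = Σ_c area_c × w_c,  w = (0.005, 0.055, 0.3, 0.75, 1.0)

over the four cover classes and converted. Scenario builders cross the
uncertain factors (9 initialization scenarios: susceptibility threshold ×
initial conditions; 27 ecological scenarios: infill rate × wet-year
probability × acceleration divisor), a Monte Carlo runner executes 20
realizations of 30 years with common-random-number coupling across
scenarios, and ANOVA plus hierarchical partitioning attribute the variance
in end-of-run invaded area to the factors.

Real park rasters are not required: a synthetic-landscape module generates
an autocorrelated suitability surface calibrated so that the susceptible
areas at thresholds 0.55/0.50/0.45 match 9,735 / 10,845 / 12,013 ha on the
default 20,000-ha desert, and places the initial cover-class areas
(178.8 / 818.3 / 503 / 121.8 ha at moderate initialization) as clustered
patches.

## Worked example

```r
library(buffelsim)

# full-scale synthetic landscape, moderate initialization
ls <- build_landscape(seed = 1)
ls
#> <bg_landscape> 210 x 400 cells (0.25 ha each, 20500.0 ha simulated)
#> state-class areas (ha):
#>   uninvaded    seedbank   cover_lt1  cover_1_10 cover_10_50  cover_gt50
#>    18878.25        0.00      178.75      818.25      503.00      121.75
#>   converted
#>        0.00
sum(ls$stratum == STRATA[["susceptible_desert"]]) * 0.25
#> [1] 10845            # calibrated susceptible area at threshold 0.50, ha
invaded_area(state_class_areas(ls))
#> [1] 288.11           # midpoint-weighted invaded area at year 0, ha
```

The initial invaded area is the class areas times the midpoint weights
(the cell-rounded analog of 178.8×0.005 + 818.3×0.055 + 503×0.3 +
121.8×0.75 = 288.15 ha).

Run a small ensemble and attribute variance (a 100×100 grid keeps this at
a few seconds):

```r
cfg <- landscape_config(ncol = 100, desert_rows = 90)
specs <- Filter(function(s) s$accel == "moderate",
                build_ecological_scenarios(horizon = 15, n_reps = 3, seed = 1))
tab <- run_scenarios(specs, landscape_config = cfg)
last <- tab[tab$year == 15, ]
hierarchical_partition(last$invaded_ha, last[c("infill", "wet_prob")])
#> <bg_partition> full-model R^2 = 0.9141
#>          independent joint share_pct
#> infill        0.7264     0      79.5
#> wet_prob      0.1877     0      20.5
```

Here the patch infill rate explains ~80% of the variance in end-of-run
invaded area and the wet-year probability ~20% — the infill rate is the
uncertainty worth reducing first. End-of-run invaded area in this small
experiment ranges from 85.6 ha (dry-slow corner) to 280.0 ha (wet-fast
corner), the scaled-down analog of the strong dry-slow vs wet-fast
divergence the full design shows.

A thin command-line wrapper over the same functions ships in
`inst/cli/buffelsim` (`generate-landscape`, `run`, `analyze`), and run
configuration is a validated YAML file (see `default_config()`).

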