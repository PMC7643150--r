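Package: buffelsim
Title: State-and-Transition Simulation of Buffelgrass Invasion with Fire Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the spread and patch infill of invasive buffelgrass
    (Cenchrus ciliaris) on a gridded desert landscape with a state-and-transition
    model coupled to a stochastic cellular fire-spread surrogate. Provides a
    synthetic-landscape generator (autocorrelated habitat suitability, strata,
    calibrated susceptibility thresholds, clustered initial cover), annual
    transition dynamics (seed dispersal, seedbank establishment and mortality,
    age-based cover-class infill with wet-year acceleration), wet-year schedule
    generation, factorial scenario builders with a Monte Carlo ensemble runner,
    and analysis tools (midpoint-weighted invaded area, burned-area metrics,
    ANOVA variance decomposition, and hierarchical partitioning of explained
    variance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
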