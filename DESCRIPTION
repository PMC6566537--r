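Package: acidrop
Title: Acidity Drop Modelling and Harvestability Windows for Clementine Orchards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal orchard-maturity monitoring of clementine
    under no-degreening production rules. Aggregates per-tree caliber and
    color-class frequencies and ten-fruit laboratory samples to plot-level
    series (mean titratable acidity, percent orange fruit, mean fruit weight),
    centers each plot's acidity trajectory at the interpolated date where
    acidity falls to 1.4 g citric acid/100 g juice, fits a pooled
    three-parameter asymptotic decay model of the acidity drop, locates
    percent-orange color milestones, and derives per-plot harvestability
    windows under acidity bounds (default 0.65-1.4). Includes a synthetic
    orchard-monitoring generator with known ground truth for parameter-recovery
    simulation, plus signed-R2 association summaries, coefficients of
    variation and year-comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
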