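Package: trophr
Title: Lotka-Volterra Framework for Herbivore-to-Producer Biomass Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the herbivore-to-producer (H/P) biomass
    ratio of plankton communities with a Lotka-Volterra-based log-linear
    framework. Simulates producer-herbivore dynamics (Lotka-Volterra and
    Rosenzweig-MacArthur variants), derives the four ecological factors
    (producer stoichiometry, edibility, specific production rate, relative
    carnivore abundance) from field-style raw measurements (PAR depth
    profiles, photosynthesis-irradiance curves, plankton counts, trap
    catches), and fits the log-linear factor model with residual-resampling
    bootstrap confidence intervals, variance inflation factors, all-subsets
    AIC selection, standardized coefficients and partial regression
    leverage analysis. A seeded synthetic pond-campaign generator with
    known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    minpack.lm,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
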