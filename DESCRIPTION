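Package: cbenefit
Title: Carbon Benefits of Natural Succession Versus Short-Rotation-Coppice Bioenergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares cumulative per-hectare carbon benefits of letting former
    cropland revert to natural vegetation (natural succession) against planting
    short rotation coppice (SRC) for bioenergy, using IPCC Tier 1 carbon
    stock-change accounting. Implements annual trajectories of the four carbon
    pools (above- and belowground biomass, dead organic matter, soil organic
    carbon) under gradual, age-cohort land conversion; linear-capped, logistic
    and Chapman-Richards regrowth curves; displacement factors computed from
    conversion efficiencies and emission factors with optional upstream
    emissions; closed-form and time-resolved fossil-fuel displacement;
    area-weighted regional aggregation of biophysical strata; Monte Carlo
    sensitivity analysis of plantation yields; and scenario runs with
    time-varying displacement factors. Ships seeded synthetic-data generators
    and a small illustrative (non-normative) parameter catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
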