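Package: lichenline
Title: Reconstructing and Modelling Reindeer Forage-Lichen Biomass from
    Heterogeneous Greyscale Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing reindeer forage-lichen cover and dry
    biomass from multi-sensor single-band (greyscale) imagery, and for
    modelling herding-district lichen biomass dynamics under reindeer
    grazing. Includes pseudo-invariant-feature radiometric calibration of
    heterogeneous scenes to a common reference, plot-trained linear cover
    and biomass regressions with clamping, zonal border comparisons and
    district means, a resolution-rescaling diagnostic, weighted mean
    absolute percent error validation, and a discrete-time mechanistic
    biomass model (density-dependent growth with a Jensen-type landscape
    correction, metabolic intake, and density-proportional loss) with
    loss-parameter estimation. A seeded synthetic-landscape generator
    makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
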