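Package: trunkload
Title: Mechanistic Models of Elephant Trunkload Mass Across Savanna Forage Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the dry mass of forage an African savanna elephant
    (Loxodonta africana) gathers per trunkload -- the elephant analogue of
    bite mass -- for five forage types (green grass, mixed green and dry
    grass, green forbs, green leaves and canopy bark from woody plants) and
    two elephant groups (adult bulls and members of breeding herds).
    Provides allometric model fitting (zero-intercept tuft mass on height x
    basal area, linear leaf-trunkload on leaf-unit mass, quadratic bark mass
    on branch length x diameter), tuft-selection ceilings, smoothing-spline
    interpolation of quarterly grass and forb height surveys to a daily
    time step, a daily landscape-unit-resolved model run over a unit-ID
    raster with area-weighted summaries, paired nonparametric comparisons of
    the resulting time series, and a fully parameterised synthetic
    field-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
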