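Package: venomclim
Title: Bioclimatic Regression Modelling and Predictive Mapping of Snake
    Venom Enzymatic Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links venom enzymatic phenotypes to climate. Computes seven
    bioclimatic indices (annual means, ranges, isothermality and
    coefficient-of-variation seasonality measures) from monthly
    temperature and precipitation grids; reduces enzymatic assay
    readouts (standard curves, kinetic rates, relative proteolysis) to
    per-sample specific activities; fits transformation-gridded simple
    and multiple linear regressions with backward stepwise refinement
    and diagnostic gating (Shapiro-Wilk, Breusch-Pagan, Rainbow,
    variance inflation factors); checks spatial non-stationarity with
    geographically weighted regression; and projects selected models
    pixel-wise over raster covariate stacks into predictive venom
    phenotype maps. Includes a fully seeded synthetic-data generator
    (climate fields, sampling sites, activities with known ground
    truth) so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    lmtest,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
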