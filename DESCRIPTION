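Package: soctraits
Title: Tree Functional Traits, Stand Biomass, and Forest Soil Organic Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stand-level analysis of forest soil organic carbon
    (SOC): harmonisation of heterogeneous soil-profile measurements onto an
    equivalent-soil-mass (ESM) grid with pedo-transfer bulk-density
    estimation, composite study-reliability weights, site-relative log
    response-ratio normalisation, plant-economics-spectrum (PES) and biomass
    indices from imputation-based PCA of species traits, clade-age
    phylogenetic distances, mixture overyielding indices, and a weighted
    trait-by-biomass-by-site inference layer with permutation-importance
    driver ranking and forward-AIC interaction models. Includes a
    multi-site common-garden synthetic data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    lme4,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
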