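Package: pacermca
Title: Passenger-Approximated Clonal Expansion Rates for Mosaic
    Chromosomal Alterations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-individual clonal expansion rates for mosaic
    chromosomal alterations (mCAs) detected in blood whole-genome
    sequencing, using clock-like passenger mutation counts as a molecular
    clock. Implements MoChA-style mCA call filtering and cohort
    definition, clock-like somatic passenger counting, covariate-adjusted
    expansion-rate (PACER) scoring via negative binomial regression with
    Yeo-Johnson inverse-normal residual transformation, per-mCA fitness
    aggregation with fold changes against loss of chromosome X, blood
    count and germline variant association analyses, and a synthetic
    clonal-expansion cohort generator for end-to-end validation without
    restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
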