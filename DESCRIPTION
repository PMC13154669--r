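Package: pelletpop
Title: Quantitative Morphology of Fungal-Bacterial Pellet Populations in Co-Culture Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated analysis of stereo-microscopy images of shake-flask
    co-cultures of pellet-forming filamentous microorganisms (Aspergillus
    niger and Streptomyces coelicolor). Segments pellets by multi-level
    Otsu thresholding and a combined-surface marker-controlled watershed,
    separates touching pellets via dark-core markers, computes per-pellet
    morphometric features, classifies particles into fungal pellets,
    bacterial pellets and bacterial aggregates with a configurable rule
    table, and summarises populations (number-frequency size
    distributions, D10/D50/D90, normalized span width, concentration,
    aggregation frequency). Includes a seeded synthetic-image generator
    with full ground truth for end-to-end validation, shake-flask maximum
    oxygen transfer rate correlations for baffled and non-baffled flasks,
    and growth-kinetics parameter estimation from cultivation time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
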