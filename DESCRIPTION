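Package: pollenrisk
Title: Pesticide Risk Assessment for Honey Bees from Pollen Residues,
    Spray Records and Landscape Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pesticide risk to honey bee colonies
    providing crop pollination services. Computes Pollen Hazard Quotients
    (PHQ) from beebread residue concentrations and route-specific honey
    bee LD50 values, converts them to percent-of-LD50 exposure under
    standard contact and chronic-oral assumptions, and classifies sites
    against EPA and EFSA levels of concern. Also computes the spray-record
    based Pesticide Use Index (PUI), attributes site risk to compounds
    sprayed or not sprayed during bloom, derives pollen morphotype
    composition metrics (relative abundance, sporadic-pollen pooling,
    focal-crop fraction, richness), summarises land-cover composition in
    circular buffers around apiary sites with AIC-based spatial scale
    selection, and generates calibrated synthetic orchard studies for
    validating the full analysis pipeline.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
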