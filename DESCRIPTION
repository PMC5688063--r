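Package: potbiomass
Title: Counterfactual Potential Above-Ground Biomass Reconstruction on Gridded Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs annual potential above-ground biomass (AGB) over a
    gridded domain by training a bagged ensemble of model trees (decision
    trees with multiple-linear-regression leaves) on intact-forest pixels,
    using a static monthly climatology and latitude as predictors. Derives
    the human-driven biomass deficit (potential minus observed AGB) with
    percentile-ensemble confidence ranges, area-weighted basin totals,
    segment trends, ENSO winter-composite correlations, pixelwise
    land-use correlation maps, and out-of-sample intact-forest validation.
    Ships a synthetic-world generator with known ground truth so the whole
    pipeline is testable without external satellite or climate products.
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
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
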