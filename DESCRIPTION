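Package: nutrientcolor
Title: Nutrient-Color Classification and Change Analysis for Lake Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the two-axis nutrient-color assessment of lake
    populations from national probability surveys. Classifies lakes as blue,
    green, brown, or murky from total phosphorus and true water color;
    estimates design-weighted class proportions with a local-neighborhood
    variance estimator and tests change between repeated surveys; summarises
    per-lake change vectors in (TP, color) space with circular statistics
    (mean direction, bootstrap confidence arcs, Rao spacing test); processes
    phytoplankton and zooplankton count tables into community matrices and
    biomass ratios; and compares lake classes with Kruskal-Wallis/Dunn tests,
    Bray-Curtis dissimilarity, PERMANOVA and non-metric multidimensional
    scaling. Includes a calibrated synthetic survey generator so every stage
    can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
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
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
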