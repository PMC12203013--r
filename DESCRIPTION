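Package: pelletdiet
Title: Owl-Pellet Diet Reconstruction and Detection-Effort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing small-mammal and bird prey communities
    from barn-owl pellet dissections: minimum-number-of-individuals (MNI)
    counts from paired skeletal elements, Index of Relative Importance (IRI)
    diet ranking, Shannon diversity and Pielou evenness, binomial
    detection-probability curves and minimum pellet effort for confident
    detection of a target taxon, abundance- and incidence-based rarefaction
    and extrapolation of species richness with Chao asymptotic estimators,
    and pairwise Fisher exact tests of community and habitat composition
    with Bonferroni adjustment. Includes a synthetic pellet-study generator
    with known ground truth for power analysis and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
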