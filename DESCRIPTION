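Package: coralfd
Title: Trait-Based Functional Diversity of Coral Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the structural complexity of coral assemblages from
    colony morphology. Species are coded on eight binary growth-form traits
    (arborescent, bushy, table, foliose, column, massive, encrusting,
    unattached), collapsed into functional entities (unique trait
    combinations), and embedded in a morpho-functional space by principal
    coordinates analysis of Gower dissimilarities with Cailliez correction.
    Per-transect cover data yield community-weighted trait means, convex-hull
    functional richness, evenness, divergence, dispersion and Rao quadratic
    entropy, plus functional redundancy, vulnerability and over-redundancy
    with constrained permutation null models, standardized effect sizes and
    quantile p-values. Includes year-by-year inference (Welch and paired
    t-tests, multiplicity adjustment, richness correlations), a synthetic
    disturbance/recovery data generator, and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
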