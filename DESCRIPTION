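Package: crossvar
Title: Gene-Level Partitioning of Expression Variance Across Organs and Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies, gene by gene, how much expression variation in a
    balanced multi-organ, multi-species RNA-seq compendium is attributable to
    organ, to species, and to residual noise, using the closed-form balanced
    two-factor ANOVA decomposition. Classifies genes into tissue-variable
    (TVG), species-variable (SVG), other unconstrained and constrained classes
    from dynamic-range and variance-proportion thresholds; measures organ- vs
    species-dominated clustering of samples with Newman modularity of
    thresholded correlation networks; selects the most informative genes for
    PCA with the permutation-based projection score; and provides the matching
    hierarchical-clustering and PCA conventions. Includes a synthetic-data
    generator with phylogenetically structured (Brownian-motion) species
    effects and known per-gene variance components for ground-truth testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
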