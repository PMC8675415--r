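Package: brainvar
Title: Sex Differences in the Variability of Brain Morphometry Across the
    Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A mega-analytic pipeline for studying male-female differences
    in the mean and, especially, the variability of regional brain
    morphometry (subcortical volumes, cortical surface area and thickness
    on the Desikan-Killiany parcellation) pooled across many imaging
    cohorts spanning the lifespan.  Provides two-step covariate
    harmonization (cubic-age linear model followed by random-forest
    adjustment for scanner field strength and segmentation-software
    version), permutation tests of the male/female variance ratio with
    false-discovery-rate control, shift functions (decile distance
    functions with bootstrap confidence intervals) describing where along
    the distribution the sexes differ, absolute-residual regressions
    testing whether the variance gap changes with age, comparison of
    sex-specific inter-regional anatomical correlation matrices, and a
    seeded multi-cohort synthetic-data generator with known ground truth
    for validating every stage.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
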