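Package: essiv
Title: Twin-Based Screening for Epigenetic Supersimilarity and Systemic
    Interindividual Variation in DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for screening array-scale DNA methylation data for
    epigenetic supersimilarity (ESS) in twin pairs and systemic interindividual
    variation (SIV) across tissues, the two signatures of methylation states
    established stochastically in the cleavage-stage embryo. Implements
    probe-level twin-pair mean squared error with randomized-pair
    normalization, ESS and SIV classification with negative-control selection,
    probe-set enrichment statistics, genotype-methylation association and
    variance-heterogeneity tests, a season-of-conception epigenome-wide
    association stage with robust regression, and a cluster-level permutation
    framework linking baseline blood methylation to later cancer risk in
    matched case-control studies. Ships synthetic-data generators that embody
    the early-embryo establishment model, so every stage can be exercised and
    validated against ground truth without access to cohort data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
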