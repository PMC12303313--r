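Package: cocultr
Title: Co-Culture Metabolomics Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for non-contact co-culture metabolomics of two
    microalgae (a diatom and a haptophyte): LC-MS feature-table preprocessing
    (log transform, normal-tail presence/absence cutoff), chemodiversity
    (Shannon index) and PCA ordination including a combined-monoculture
    comparison, PLS-VIP differential-feature selection with cross-validated
    component tuning, MS1-to-MS2 annotation linking through data-dependent
    acquisition inclusion lists, MSI confidence-level tallies, suspect-list
    screening, metabolic-exchange classification across culture conditions,
    growth-curve statistics (two-way ANOVA with replication, Welch t-tests),
    and a synthetic-data generator with planted ground truth for recovery
    testing.
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
    stringr,
    tools,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineOB,
    cluster,
    mixOmics,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
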