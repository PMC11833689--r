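Package: chromage
Title: Gene Evolutionary Age, Chromatin Assortativity and Pol II Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking gene evolutionary age (phylostratigraphy age
    classes grouped into unicellular, early-metazoan and mammal-specific
    categories) to chromatin regulation and 3D genome organization.
    Builds fragment-contact networks from promoter-capture Hi-C interaction
    calls, annotates genes with age categories, Polycomb targets,
    lamina-associated-domain overlap, promoter CpG density and methylation,
    computes chromatin assortativity (ChAs) with distance-matched
    randomization nulls and z-scores, the delta-ChAs statistic contrasting
    feature-positive and feature-negative gene subgroups, and the RNA
    polymerase II pausing-index pipeline with its outlier, expression and
    gene-length filters.  A synthetic-data generator with planted ground
    truth (edge assortativity, pausing ratios, age trends) supports
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
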