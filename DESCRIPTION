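Package: metaboqtl
Title: Metabolite QTL Mapping in Recombinant Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative-genetic analysis of targeted metabolomics in
    two-parent recombinant inbred line (RIL) panels. Implements the full
    normalization chain for compositional metabolite data (detection-limit
    filtering, per-class composition ratios, batch correction, z-scoring,
    per-strain outlier removal), transgressive-segregation and broad-sense
    heritability tests with permutation-based false discovery thresholds,
    single-marker, additive multi-marker and two-locus epistasis genome
    scans with a permutation threshold under dependency, 1.5-drop
    confidence intervals, simulation-based power analysis over a genetic
    map, and confirmation plus region narrowing of QTL with introgression
    lines. Includes a synthetic-data generator that emulates the design of
    a replicated RIL metabolomics experiment so every stage can be tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
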