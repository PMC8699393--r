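Package: lineagepump
Title: Lineage-Aware Analysis of Intercellular Fluorescence Transfer in
    Co-Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for relating fibroblast-to-cancer-cell fluorescence
    transfer ("cell-projection pumping") to recipient-cell phenotype in
    time-lapse co-culture recordings.  Provides a lineage forest data model
    for tracked cells, readers and writers for long-format track tables,
    morphometrics (cell-profile area, perimeter, circularity, masked
    fluorescence), absolute and mother-compensated fluorescence accounting
    (Fa, Fmc) with uptake rates, migration velocity on a 2-h centroid grid,
    generation-grouped Kendall tau-b correlations, sister-pair difference
    analysis, dividing versus non-dividing comparisons (pFa, pFmc), a
    persistence index deciding whether phenotypic effects of fluorescence
    receipt survive mitosis, and an agent-based co-culture simulator with
    known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
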