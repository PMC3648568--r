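Package: qtlconverge
Title: Convergent QTL and Transcriptome Meta-Analysis for Yield Under Drought
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the convergent analysis of quantitative trait loci
    (QTL) and transcriptome data in backcross inbred line (BIL) systems,
    motivated by grain-yield-under-drought QTL mapping in rice.  Provides
    sliding-window aggregation scans that locate genome blocks enriched
    for differentially expressed genes or differentially hybridized array
    probes, Fisher-exact enrichment of gene sets within QTL intervals and
    annotation categories, regression-based (Haley-Knott) QTL interval
    and composite-interval scans with empirical permutation thresholds,
    candidate-gene nomination at the intersection of all three lines of
    evidence, and multi-environment trial yield-advantage summaries.  A
    synthetic-data module simulates every input the pipeline consumes
    (positioned gene catalogs, expression and hybridization matrices,
    backcross-derived mapping populations, trial tables) with known
    planted structure, so the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
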