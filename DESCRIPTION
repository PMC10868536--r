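Package: featuregp
Title: Feature-Partitioned Genomic Prediction with GBLUP and GFBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits with single-component
    GBLUP and two-component genomic-feature BLUP (GFBLUP). Provides phenotype
    adjustment of pig growth traits to a 100 kg endpoint, genotype quality
    control (call rate, minor allele frequency, exact Hardy-Weinberg test),
    positional variant-consequence classification from gene models,
    VanRaden genomic relationship matrices and identity-by-state similarity,
    restricted maximum likelihood variance components (profiled single
    component and average-information two component), mixed-linear-model
    association scans with an N/M false-discovery-rate preselection rule,
    cross-validated prediction accuracy, and a two-population genotype and
    phenotype simulator with linkage disequilibrium and class-enriched
    quantitative trait loci for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
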