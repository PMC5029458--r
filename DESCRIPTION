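Package: raex
Title: Random Allelic Expression Imbalance in Clonal Cell Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calls allele-specific expression from two-channel SNP-array
    intensities of paired genomic DNA and cDNA samples, classifies genes as
    biallelic, skewed or monoallelic from gene-level delta-beta scores,
    detects random allelic expression imbalance across sister clones and
    developmental states, estimates its genome-wide frequency with clonal
    and polyclonal estimators, and relates allelic status to region-level
    DNA methylation differences. Includes exact Wilcoxon and Fisher
    gene-set statistics and a seeded synthetic-data generator with known
    ground truth for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    limma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
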