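Package: germpanel
Title: Germline Variant Analysis for Targeted Cancer-Predisposition Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis engine for hybridization-capture cancer-predisposition
    gene panels sequenced at high depth: per-exon and flanking-intron coverage
    quality control with a minimum-position coverage rule, union merging of two
    variant callers with depth/allele-fraction filters, exon-level germline
    copy-number calling against a pool of reference diploid normals,
    breakpoint refinement of coverage-derived CNVs using structural-variant
    evidence, five-class ACMG variant classification with the BA1 stand-alone
    benign rule, and assay-validation statistics (exact binomial detection
    power, false-positive threshold characterization, replicate concordance).
    Includes a seeded synthetic-data generator that emulates panel coverage
    and call sets with planted ground truth, so every component is testable
    without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
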