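Package: gistcin
Title: Chromosomal Instability Scoring and Multi-Omics Integration for GIST Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromosome-level chromosomal-instability (CIN) scoring and
    simple/complex karyotype classification from allele-specific copy-number
    segment profiles (FACETS-style input), windowed chromothripsis detection by
    copy-number state switch counting, rule-based classification of the
    allele-specific expression of somatic mutations from RNA evidence,
    threshold-based mRNA/miRNA expression filtering with opposite-fold-change
    miRNA-mRNA target pairing, and exact small-sample Mann-Whitney group
    comparisons. Includes a synthetic-data generator that plants known ground
    truth (aberrant chromosome counts, chromothriptic switch patterns, ASE
    classes, anti-correlated miRNA-mRNA pairs) so every stage is testable
    without access to raw sequencing data, and a bundled 21-sample gastric
    GIST reference cohort summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
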