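Package: genoscreen
Title: Genome-First Screening Analysis for Recessive Disease in EHR-Linked Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-first screening of an autosomal-recessive
    condition (modelled on cystic fibrosis and the CFTR locus) in large
    cohorts with linked electronic health records. Resolves variant
    pathogenicity from curated assertion tables (CFTR2-style and
    ClinVar-style snapshots), calls bi-allelic screen positives from cohort
    genotypes, cross-references ICD-10 diagnosis codes, adjudicates
    true/false positives and negatives against rule-based chart-review
    criteria, and computes screening performance statistics with exact
    Clopper-Pearson confidence intervals. Includes a seeded synthetic-cohort
    generator with Hardy-Weinberg recessive genetics and imperfect EHR
    phenotyping so the full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
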