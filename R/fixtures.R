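#' Packaged case-study knowledge base
#'
#' Loads the packaged CFTR2-style and ClinVar-style assertion snapshots
#' for the 14 CFTR alleles of the worked case study (12 CFTR2 assertions
#' and 13 ClinVar assertions; one allele, R1239S, is absent from both -
#' a genuinely novel pathogenic allele at the time of the snapshots, and
#' the screen's one false-negative mechanism). Genomic coordinates in the
#' fixture are synthetic placeholders on chromosome 7 derived from the
#' cDNA offsets; classifications, names and review stars encode the
#' curated record. The one dated assertion is Q1476X (ClinVar, 2013), so
#' era-restricted queries before 2013 return `UNKNOWN` for it.
#'
#' @param snapshot_date Snapshot date of the loaded tables.
#' @return A `variant_kb`.
#' @export
kb_fixture <- function(snapshot_date = "2018-09-15") {
  load_kb(gs_extdata("kb_cftr2.tsv"), gs_extdata("kb_clinvar.tsv"),
          snapshot_date = snapshot_date)
}

#' Packaged case-study cohort
#'
#' The worked case study of a genome-first CF screen over 50,778 exomes:
#' 26 chart-reviewed individuals (24 bi-allelic screen positives and 2
#' heterozygotes surfaced by their diagnosis codes), 6 additional
#' code-positive individuals with no pathogenic variants, and
#' variant-free padding to the requested cohort size. Genotypes, sweat
#' chloride results, clinical test results, structured chart facts and
#' ICD-10 codes are encoded in plain-text fixtures under `extdata`;
#' padding ages/sexes and the six code-positive individuals' demographics
#' are synthetic.
#'
#' @param n_total Total cohort size after padding (default 50778; use a
#'   small value for quick examples).
#' @return A `gs_cohort`.
#' @export
cohort_fixture <- function(n_total = 50778) {
  cohort <- read_cohort(
    vcf_path = gs_extdata("cohort_cases.vcf"),
    manifest_path = gs_extdata("cohort_manifest.tsv"),
    codes_path = gs_extdata("cohort_codes.tsv"),
    chart_path = gs_extdata("cohort_chart.tsv"),
    clinical_path = gs_extdata("cohort_clinical.tsv")
  )
  pad_cohort(cohort, n_total)
}

#' Legacy names on a 2004-era 23-variant carrier panel
#'
#' The subset of the fixture's pathogenic alleles that appeared on the
#' historical ACMG carrier-screening panel; used for era-restricted
#' screening demonstrations.
#'
#' @return Character vector of legacy names.
#' @export
acmg_panel_2004 <- function() {
  c("F508del", "G542X", "G551D", "R117H", "R334W")
}

gs_extdata <- function(file) {
  path <- system.file("extdata", file, package = "genoscreen")
  if (path == "") abort(paste0("fixture file not found: ", file))
  path
}
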