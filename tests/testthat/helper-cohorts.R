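# Builders for small in-memory cohorts and knowledge bases used by the
# unit tests (all fixtures are constructed in code).

# knowledge base over four toy alleles with one call of each kind:
# VP1/VP2 pathogenic, VB benign, VU present nowhere (unknown)
toy_kb <- function(snapshot_date = "2020-01-01") {
  cftr2 <- tibble::tibble(
    legacy_name = c("VP1", "VP2", "VB"),
    cdna_name = c("c.100A>T", "c.200C>G", "c.300G>A"),
    protein_name = c("p.K34X", "p.P67R", "p.G100G"),
    classification = c("CF causing", "CF causing", "Non CF-causing"),
    asserted_date = "",
    chrom = "7", pos = c(100L, 200L, 300L), ref = c("A", "C", "G"),
    alt = c("T", "G", "A")
  )
  clinvar <- cftr2 |>
    dplyr::mutate(classification = c("Pathogenic", "Likely pathogenic", "Benign"),
                  review_stars = c("4", "2", "1"))
  load_kb(cftr2, clinvar, snapshot_date = snapshot_date)
}

toy_variants <- function() {
  variant_tbl(
    chrom = "7", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("T", "G", "A", "C"),
    legacy_name = c("VP1", "VP2", "VB", "VU")
  )
}

# cohort from a compact genotype map: named list sample -> named dose
# vector over the toy variants (dose 1 = HET, 2 = HOM_ALT)
toy_cohort <- function(genotypes, codes = NULL, chart = NULL) {
  v <- toy_variants()
  calls <- purrr::imap(genotypes, function(doses, sid) {
    doses <- doses[doses > 0]
    if (length(doses) == 0) return(NULL)
    tibble::tibble(
      sample_id = sid,
      legacy_name = names(doses),
      zygosity = ifelse(doses == 2, "HOM_ALT", "HET")
    )
  })
  calls <- dplyr::bind_rows(calls)
  if (nrow(calls) > 0) {
    calls <- calls |>
      dplyr::left_join(dplyr::select(v, "legacy_name", "variant_key"),
                       by = "legacy_name") |>
      dplyr::mutate(platform = "WES", call_date = as.Date(NA), comparable = NA) |>
      dplyr::select("sample_id", "variant_key", "legacy_name", "zygosity",
                    "platform", "call_date", "comparable")
  }
  new_cohort(
    samples = tibble::tibble(sample_id = names(genotypes),
                             age_years = 30, sex = "F"),
    variants = v,
    calls = calls,
    codes = if (is.null(codes)) tibble::tibble(sample_id = character(),
                                               icd10_code = character()) else codes,
    chart = if (is.null(chart)) tibble::tibble(
      sample_id = character(), sweat_values = character(),
      clinical_variants = character(), bronchiectasis = character(),
      pancreatic_supplement = character(), respiratory_pseudomonas = character(),
      cf_clinic_care = character(), cf_dx_in_ehr = character()) else chart
  )
}

# one uninformative chart row
blank_chart_row <- function(sample_id, ...) {
  row <- tibble::tibble(
    sample_id = sample_id, sweat_values = "-", clinical_variants = "-",
    bronchiectasis = "unknown", pancreatic_supplement = "unknown",
    respiratory_pseudomonas = "unknown", cf_clinic_care = "no",
    cf_dx_in_ehr = "no"
  )
  dots <- list(...)
  for (nm in names(dots)) row[[nm]] <- dots[[nm]]
  row
}

# small padded copy of the packaged case-study cohort (cheap to screen)
fixture_small <- function(n_total = 200) cohort_fixture(n_total = n_total)
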