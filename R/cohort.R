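#' Construct a cohort object
#'
#' A cohort bundles the tables the screening analysis needs: a sample
#' manifest, the assayed variant table, per-sample alternate-allele
#' genotype calls (homozygous-reference calls are not stored; absence
#' means reference), ICD-10 diagnosis codes, structured chart facts, and
#' any no-call (missing genotype) records used by marker QC.
#'
#' @param samples Tibble: `sample_id`, `age_years`, `sex`.
#' @param variants Tibble of assayed variants (normalized; see
#'   [variant_tbl()]).
#' @param calls Tibble: `sample_id`, `variant_key`, `legacy_name`,
#'   `zygosity` (`"HET"`/`"HOM_ALT"`), `platform` (`"WES"`, `"ARRAY"`,
#'   `"CLINICAL_PANEL"`), `call_date` (Date, `NA` allowed), `comparable`
#'   (logical; used by [platform_concordance()], `NA` for research calls).
#' @param codes Tibble: `sample_id`, `icd10_code` (normalized).
#' @param chart Tibble of chart facts (see [read_chart()]).
#' @param no_calls Tibble: `sample_id`, `variant_key`, `platform`.
#' @return An object of class `gs_cohort`.
#' @export
new_cohort <- function(samples, variants = empty_variants(), calls = empty_calls(),
                       codes = empty_codes(), chart = empty_chart(),
                       no_calls = empty_no_calls()) {
  samples <- as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicate sample_id in manifest: ",
                 samples$sample_id[duplicated(samples$sample_id)][[1L]]))
  }
  calls <- as_tibble(calls)
  if (nrow(calls) > 0L) {
    dup <- calls |> count(.data$sample_id, .data$variant_key, .data$platform) |>
      filter(.data$n > 1L)
    if (nrow(dup) > 0L) {
      abort(paste0("duplicate genotype call for sample ", dup$sample_id[[1L]],
                   ", variant ", dup$variant_key[[1L]], ", platform ",
                   dup$platform[[1L]]))
    }
    stray <- setdiff(calls$sample_id, samples$sample_id)
    if (length(stray) > 0L) {
      abort(paste0("genotype call for sample not in manifest: ", stray[[1L]]))
    }
  }
  structure(list(samples = samples, variants = as_tibble(variants),
                 calls = calls, codes = as_tibble(codes),
                 chart = as_tibble(chart), no_calls = as_tibble(no_calls)),
            class = "gs_cohort")
}

empty_variants <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), cdna_name = character(), protein_name = character(),
         legacy_name = character(), tract_modifier = character(),
         variant_key = character())
}
empty_calls <- function() {
  tibble(sample_id = character(), variant_key = character(),
         legacy_name = character(), zygosity = character(),
         platform = character(), call_date = as.Date(character()),
         comparable = logical())
}
empty_codes <- function() tibble(sample_id = character(), icd10_code = character())
empty_chart <- function() {
  tibble(sample_id = character(), sweat_values = character(),
         clinical_variants = character(), bronchiectasis = character(),
         pancreatic_supplement = character(), respiratory_pseudomonas = character(),
         cf_clinic_care = character(), cf_dx_in_ehr = character())
}
empty_no_calls <- function() {
  tibble(sample_id = character(), variant_key = character(), platform = character())
}

#' @export
print.gs_cohort <- function(x, ...) {
  cat("<gs_cohort>", nrow(x$samples), "individuals,",
      nrow(x$variants), "assayed variants,", nrow(x$calls), "stored ALT calls\n")
  if (nrow(x$calls) > 0L) print(count(x$calls, .data$platform))
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort A `gs_cohort`.
#' @return Integer cohort size.
#' @export
cohort_size <- function(cohort) nrow(cohort$samples)

#' Read a cohort from files
#'
#' Loads genotypes from a minimal VCF (v4.2, `GT` format field), the
#' sample manifest, and optional ICD-10 code, chart-fact and clinical
#' genetic-test tables. Every alternate-allele genotype in the VCF becomes
#' a stored call (`0/1` -> HET, `1/1` -> HOM_ALT); `./.` genotypes are
#' recorded as no-calls for marker QC; `0/0` is not stored. Variant
#' legacy names are taken from the VCF `ID` column.
#'
#' @param vcf_path Path to the VCF (plain or bgzipped).
#' @param manifest_path TSV: `sample_id`, `age_years`, `sex`. Must cover
#'   every VCF sample column.
#' @param codes_path Optional TSV: `sample_id`, `icd10_code`. A sample in
#'   the codes table but not in the VCF/manifest is a hard error.
#' @param chart_path Optional chart-fact TSV (see [read_chart()]).
#' @param clinical_path Optional TSV of clinical genetic-test calls:
#'   `sample_id`, `legacy_name`, `zygosity`, `call_date`, `comparable`.
#' @return A `gs_cohort`.
#' @export
read_cohort <- function(vcf_path, manifest_path, codes_path = NULL,
                        chart_path = NULL, clinical_path = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- normalize_variants(tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    cdna_name = "", protein_name = "",
    legacy_name = dplyr::coalesce(fix$ID, ""), tract_modifier = ""
  ))
  manifest <- readr::read_tsv(manifest_path, col_types = readr::cols(
    sample_id = readr::col_character(), age_years = readr::col_double(),
    sex = readr::col_character()), progress = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt)
  missing_from_manifest <- setdiff(vcf_samples, manifest$sample_id)
  if (length(missing_from_manifest) > 0L) {
    abort(paste0("VCF sample missing from manifest: ", missing_from_manifest[[1L]]))
  }

  calls <- empty_calls()
  no_calls <- empty_no_calls()
  if (!is.null(gt) && nrow(gt) > 0L) {
    long <- tibble(
      variant_key = rep(variants$variant_key, times = ncol(gt)),
      legacy_name = rep(variants$legacy_name, times = ncol(gt)),
      sample_id = rep(vcf_samples, each = nrow(gt)),
      gt = as.vector(gt)
    )
    long$dose <- gt_dose(long$gt, long$variant_key, long$sample_id)
    no_calls <- long |> filter(is.na(.data$dose)) |>
      mutate(platform = "WES") |> select("sample_id", "variant_key", "platform")
    calls <- long |>
      filter(!is.na(.data$dose), .data$dose > 0L) |>
      mutate(zygosity = if_else(.data$dose == 2L, "HOM_ALT", "HET"),
             platform = "WES", call_date = as.Date(NA), comparable = NA) |>
      select("sample_id", "variant_key", "legacy_name", "zygosity",
             "platform", "call_date", "comparable")
  }

  codes <- empty_codes()
  if (!is.null(codes_path)) {
    codes <- readr::read_tsv(codes_path, col_types = readr::cols(
      sample_id = readr::col_character(), icd10_code = readr::col_character()),
      progress = FALSE)
    stray <- setdiff(codes$sample_id, manifest$sample_id)
    if (length(stray) > 0L) {
      abort(paste0("sample in codes table but not in cohort: ", stray[[1L]]))
    }
    codes$icd10_code <- normalize_icd10(codes$icd10_code)
  }

  chart <- if (is.null(chart_path)) empty_chart() else read_chart(chart_path)
  if (nrow(chart) > 0L) {
    stray <- setdiff(chart$sample_id, manifest$sample_id)
    if (length(stray) > 0L) {
      abort(paste0("sample in chart table but not in cohort: ", stray[[1L]]))
    }
  }

  clinical <- empty_calls()
  if (!is.null(clinical_path)) {
    cl <- readr::read_tsv(clinical_path, col_types = readr::cols(
      sample_id = readr::col_character(), legacy_name = readr::col_character(),
      zygosity = readr::col_character(), call_date = readr::col_date(),
      comparable = readr::col_character()), progress = FALSE)
    stray <- setdiff(cl$sample_id, manifest$sample_id)
    if (length(stray) > 0L) {
      abort(paste0("sample in clinical table but not in cohort: ", stray[[1L]]))
    }
    clinical <- cl |>
      left_join(select(variants, "legacy_name", "variant_key"), by = "legacy_name") |>
      mutate(variant_key = dplyr::coalesce(.data$variant_key,
                                           paste0("name:", .data$legacy_name)),
             platform = "CLINICAL_PANEL",
             comparable = tolower(.data$comparable) %in% c("yes", "true", "1")) |>
      select("sample_id", "variant_key", "legacy_name", "zygosity",
             "platform", "call_date", "comparable")
  }

  new_cohort(samples = manifest, variants = variants,
             calls = bind_rows(calls, clinical), codes = codes, chart = chart,
             no_calls = no_calls)
}

# GT string -> ALT dose (0/1/2), NA for missing; anything else is an error
gt_dose <- function(gt, variant_key, sample_id) {
  gt <- sub("\\|", "/", gt)
  dose <- dplyr::case_match(gt,
    c("0/0", "0") ~ 0L,
    c("0/1", "1/0") ~ 1L,
    c("1/1", "1") ~ 2L,
    c("./.", ".", NA) ~ NA_integer_,
    .default = -1L
  )
  bad <- which(dose == -1L)
  if (length(bad) > 0L) {
    abort(paste0("unparseable GT '", gt[[bad[[1L]]]], "' at ",
                 variant_key[[bad[[1L]]]], ", sample ", sample_id[[bad[[1L]]]]))
  }
  dose
}

#' Read a chart-fact table
#'
#' Chart facts are the structured output of open chart review, one row per
#' reviewed individual: sweat chloride results (`sweat_values`, a
#' semicolon list; `QNS` marks an attempted test with insufficient
#' quantity and is treated as no usable value; a leading `<` keeps
#' below-detection results, e.g. `<10`), clinical genetic-test variants
#' (`clinical_variants`, semicolon list of legacy names or `-`), and
#' yes/no/unknown flags: `bronchiectasis`, `pancreatic_supplement`,
#' `respiratory_pseudomonas`, `cf_clinic_care` (longitudinal care by CF
#' physicians, at this or an outside centre) and `cf_dx_in_ehr`
#' (a CF diagnosis documented in the EHR problem list).
#'
#' @param path TSV path.
#' @return Tibble of chart facts.
#' @export
read_chart <- function(path) {
  chart <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  need <- names(empty_chart())
  missing <- setdiff(need, names(chart))
  if (length(missing) > 0L) {
    abort(paste0("chart table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("bronchiectasis", "pancreatic_supplement",
                "respiratory_pseudomonas", "cf_clinic_care", "cf_dx_in_ehr")) {
    chart[[col]] <- tolower(dplyr::coalesce(chart[[col]], "unknown"))
    bad <- setdiff(unique(chart[[col]]), c("yes", "no", "unknown"))
    if (length(bad) > 0L) {
      abort(paste0("chart column ", col, " has value(s) outside yes/no/unknown: ",
                   paste(bad, collapse = ", ")))
    }
  }
  chart
}

#' Parse a sweat-chloride value list
#'
#' @param x Character vector of semicolon lists (`"93"`, `"<10;14"`,
#'   `"QNS"`, `"-"` or `NA`).
#' @return List of numeric vectors (possibly empty). `QNS` and `-` yield
#'   no values; `<k` is parsed as `k` (only ever compared against the
#'   60 mmol/L diagnostic threshold, which such results are always below).
#' @export
parse_sweat_values <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || s %in% c("", "-", "ND")) return(numeric())
    parts <- trimws(strsplit(s, ";")[[1]])
    parts <- parts[!toupper(parts) %in% c("QNS", "ND", "-", "")]
    if (length(parts) == 0L) return(numeric())
    vals <- suppressWarnings(as.numeric(sub("^<", "", parts)))
    if (anyNA(vals)) abort(paste0("unparseable sweat chloride value in '", s, "'"))
    if (any(vals < 0)) abort("sweat chloride values must be >= 0")
    vals
  })
}

#' Normalize ICD-10 code strings
#'
#' Uppercases and dot-normalizes (`"e840"` -> `"E84.0"`).
#'
#' @param x Character vector of codes.
#' @return Normalized character vector.
#' @export
normalize_icd10 <- function(x) {
  x <- toupper(trimws(x))
  no_dot <- !grepl("\\.", x) & nchar(x) > 3L
  x[no_dot] <- paste0(substr(x[no_dot], 1L, 3L), ".",
                      substr(x[no_dot], 4L, nchar(x[no_dot])))
  x
}

#' Write a cohort back to files
#'
#' Inverse of [read_cohort()]: writes `cohort.vcf.gz` (via
#' [vcfR::write.vcf()]), `manifest.tsv`, `codes.tsv`, `chart.tsv` and
#' `clinical.tsv` into `dir`. Round-tripping reproduces the stored call
#' set exactly.
#'
#' @param cohort A `gs_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf.gz"),
    manifest = file.path(dir, "manifest.tsv"),
    codes = file.path(dir, "codes.tsv"),
    chart = file.path(dir, "chart.tsv"),
    clinical = file.path(dir, "clinical.tsv")
  )
  v <- cohort$variants
  wes <- filter(cohort$calls, .data$platform == "WES")
  nc <- filter(cohort$no_calls, .data$platform == "WES")
  samples <- cohort$samples$sample_id
  gt <- matrix("0/0", nrow = nrow(v), ncol = length(samples),
               dimnames = list(NULL, samples))
  if (nrow(wes) > 0L) {
    ri <- match(wes$variant_key, v$variant_key)
    ci <- match(wes$sample_id, samples)
    gt[cbind(ri, ci)] <- if_else(wes$zygosity == "HOM_ALT", "1/1", "0/1")
  }
  if (nrow(nc) > 0L) {
    gt[cbind(match(nc$variant_key, v$variant_key),
             match(nc$sample_id, samples))] <- "./."
  }
  fix <- cbind(CHROM = v$chrom, POS = as.character(v$pos), ID = v$legacy_name,
               REF = v$ref, ALT = v$alt, QUAL = ".", FILTER = "PASS", INFO = ".")
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  vcf <- methods::new("vcfR", meta = meta,
                      fix = as.matrix(fix),
                      gt = cbind(FORMAT = rep("GT", nrow(v)), gt))
  vcfR::write.vcf(vcf, file = paths$vcf)
  readr::write_tsv(cohort$samples, paths$manifest, progress = FALSE)
  readr::write_tsv(cohort$codes, paths$codes, progress = FALSE)
  readr::write_tsv(cohort$chart, paths$chart, progress = FALSE)
  clin <- cohort$calls |>
    filter(.data$platform == "CLINICAL_PANEL") |>
    mutate(comparable = if_else(.data$comparable, "yes", "no")) |>
    select("sample_id", "legacy_name", "zygosity", "call_date", "comparable")
  readr::write_tsv(clin, paths$clinical, progress = FALSE)
  invisible(paths)
}

#' Pad a cohort with reference-genotype individuals
#'
#' Embeds a small fixture in a population-scale cohort by appending
#' variant-free individuals (no stored calls, no codes, no chart rows),
#' which is exactly what a screen-negative background looks like.
#'
#' @param cohort A `gs_cohort`.
#' @param n_total Target cohort size (`>=` current size).
#' @param prefix Sample-ID prefix for padding individuals.
#' @return The padded `gs_cohort`.
#' @export
pad_cohort <- function(cohort, n_total, prefix = "PAD") {
  n_now <- cohort_size(cohort)
  if (n_total < n_now) abort("n_total is smaller than the current cohort")
  n_add <- n_total - n_now
  if (n_add == 0L) return(cohort)
  pad <- tibble(
    sample_id = sprintf("%s%06d", prefix, seq_len(n_add)),
    age_years = NA_real_, sex = NA_character_
  )
  cohort$samples <- bind_rows(cohort$samples, pad)
  cohort
}
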