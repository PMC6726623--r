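#' Screen a cohort for bi-allelic pathogenic genotypes
#'
#' The genome-first screen: each individual's stored alternate-allele
#' calls are classified against the knowledge base as of `as_of`, and
#' pathogenic alleles are counted (a homozygote contributes 2, each
#' distinct heterozygous variant 1). Status is `BIALLELIC_POSITIVE` for a
#' count `>= 2` (two distinct heterozygous pathogenic variants are assumed
#' in trans - phase is never inferred), `CARRIER` for exactly 1, and
#' `NEGATIVE` for 0. Individuals with no stored calls are `NEGATIVE`.
#'
#' @param cohort A `gs_cohort`.
#' @param kb A `variant_kb`.
#' @param as_of Classification date (default: KB snapshot date).
#' @param platform Platform whose calls drive the screen (default `"WES"`).
#' @return A tibble of class `gs_screen`, one row per individual:
#'   `sample_id`, `status`, `n_pathogenic_alleles`, `pathogenic_alleles`
#'   (readable allele list), `as_of`.
#' @examples
#' \donttest{
#' screen <- screen_cohort(cohort_fixture(n_total = 100), kb_fixture())
#' screen_summary(screen)
#' }
#' @export
screen_cohort <- function(cohort, kb, as_of = kb$snapshot_date, platform = "WES") {
  stopifnot(inherits(cohort, "gs_cohort"), inherits(kb, "variant_kb"))
  as_of <- as.Date(as_of)
  cls <- classify_variants(kb, cohort$variants, as_of = as_of)
  path_keys <- cls$variant_key[cls$call == "PATHOGENIC"]
  calls <- cohort$calls |>
    filter(.data$platform == .env$platform, .data$variant_key %in% path_keys) |>
    distinct(.data$sample_id, .data$variant_key, .keep_all = TRUE)
  per <- calls |>
    mutate(n_alleles = if_else(.data$zygosity == "HOM_ALT", 2L, 1L)) |>
    arrange(.data$sample_id, .data$variant_key) |>
    group_by(.data$sample_id) |>
    summarise(
      n_pathogenic_alleles = sum(.data$n_alleles),
      pathogenic_alleles = paste0(.data$legacy_name, "(", .data$zygosity, ")",
                                  collapse = "+"),
      .groups = "drop"
    )
  out <- cohort$samples |>
    select("sample_id") |>
    left_join(per, by = "sample_id") |>
    mutate(
      n_pathogenic_alleles = dplyr::coalesce(.data$n_pathogenic_alleles, 0L),
      pathogenic_alleles = dplyr::coalesce(.data$pathogenic_alleles, ""),
      status = case_when(
        .data$n_pathogenic_alleles >= 2L ~ "BIALLELIC_POSITIVE",
        .data$n_pathogenic_alleles == 1L ~ "CARRIER",
        TRUE ~ "NEGATIVE"
      ),
      as_of = as_of
    ) |>
    select("sample_id", "status", "n_pathogenic_alleles",
           "pathogenic_alleles", "as_of")
  class(out) <- c("gs_screen", class(out))
  out
}

#' Screen a single individual's genotype calls
#'
#' @param genotypes Data frame of one individual's alternate-allele calls:
#'   `legacy_name` (and/or coordinate columns) plus `zygosity`
#'   (`"HET"`/`"HOM_ALT"`). Duplicated identical calls are collapsed.
#' @inheritParams screen_cohort
#' @return One-row tibble: `status`, `n_pathogenic_alleles`,
#'   `pathogenic_alleles`, `as_of`.
#' @export
screen_individual <- function(genotypes, kb, as_of = kb$snapshot_date) {
  genotypes <- as_tibble(genotypes)
  has_coords <- all(c("chrom", "pos", "ref", "alt") %in% names(genotypes))
  if (has_coords) {
    genotypes <- normalize_variants(genotypes)
  } else if (!"variant_key" %in% names(genotypes)) {
    key_map <- kb$assertions |> distinct(.data$legacy_name, .data$variant_key)
    genotypes <- genotypes |>
      left_join(key_map, by = "legacy_name") |>
      mutate(variant_key = dplyr::coalesce(.data$variant_key,
                                           paste0("name:", .data$legacy_name)))
  }
  genotypes <- distinct(genotypes, .data$variant_key, .keep_all = TRUE)
  variants <- genotypes |> select(-"zygosity")
  if (!has_coords) {
    coord_map <- kb$assertions |>
      filter(!is.na(.data$variant_key)) |>
      distinct(.data$variant_key, .data$chrom, .data$pos, .data$ref, .data$alt)
    variants <- variants |> left_join(coord_map, by = "variant_key")
  }
  calls <- genotypes |>
    mutate(sample_id = "IND", platform = "WES",
           call_date = as.Date(NA), comparable = NA) |>
    select("sample_id", "variant_key", "legacy_name", "zygosity",
           "platform", "call_date", "comparable")
  cohort <- new_cohort(
    samples = tibble(sample_id = "IND", age_years = NA_real_, sex = NA_character_),
    variants = variants, calls = calls
  )
  screen_cohort(cohort, kb, as_of = as_of) |> select(-"sample_id")
}

#' Summarise screen statuses
#'
#' @param screen A `gs_screen` tibble from [screen_cohort()].
#' @return One-row tibble: `n_positive`, `n_carrier`, `n_negative`, `n`.
#' @export
screen_summary <- function(screen) {
  tibble(
    n_positive = sum(screen$status == "BIALLELIC_POSITIVE"),
    n_carrier = sum(screen$status == "CARRIER"),
    n_negative = sum(screen$status == "NEGATIVE"),
    n = nrow(screen)
  )
}

#' @export
print.gs_screen <- function(x, ...) {
  s <- screen_summary(x)
  cat("<gs_screen>", s$n, "individuals:", s$n_positive, "bi-allelic positive,",
      s$n_carrier, "carrier,", s$n_negative, "negative\n")
  NextMethod()
}

#' Bar chart of screen statuses
#'
#' @param object A `gs_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gs_screen
#' @export
autoplot.gs_screen <- function(object, ...) {
  dat <- count(as_tibble(object), .data$status)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "individuals (log scale)",
                  title = "Genome-first screen statuses") +
    ggplot2::theme_minimal()
}

#' Per-variant allele accounting for reviewed cases
#'
#' Tallies, over a set of individuals, how many alleles of each variant
#' occur in compound-heterozygous form (each heterozygous call contributes
#' 1) versus homozygous form (each homozygote contributes 2), with each
#' variant's share of the total as a fraction and to the nearest percent.
#'
#' @param cohort A `gs_cohort`.
#' @param sample_ids Individuals to tally (default: all with stored calls).
#' @param platform Calls to tally (default `"WES"`).
#' @return Tibble: `legacy_name`, `variant_key`, `n_alleles_compound_het`,
#'   `n_alleles_homozygous`, `n_alleles_total`, `fraction`, `percent`.
#' @export
allele_accounting <- function(cohort, sample_ids = NULL, platform = "WES") {
  calls <- filter(cohort$calls, .data$platform == .env$platform)
  if (!is.null(sample_ids)) calls <- filter(calls, .data$sample_id %in% sample_ids)
  if (nrow(calls) == 0L) {
    return(tibble(legacy_name = character(), variant_key = character(),
                  n_alleles_compound_het = integer(),
                  n_alleles_homozygous = integer(), n_alleles_total = integer(),
                  fraction = double(), percent = double()))
  }
  out <- calls |>
    group_by(.data$legacy_name, .data$variant_key) |>
    summarise(
      n_alleles_compound_het = sum(.data$zygosity == "HET"),
      n_alleles_homozygous = 2L * sum(.data$zygosity == "HOM_ALT"),
      .groups = "drop"
    ) |>
    mutate(n_alleles_total = .data$n_alleles_compound_het + .data$n_alleles_homozygous,
           fraction = .data$n_alleles_total / sum(.data$n_alleles_total),
           percent = round(100 * .data$fraction)) |>
    arrange(dplyr::desc(.data$n_alleles_total), .data$legacy_name)
  out
}

#' Cross-platform genotype concordance
#'
#' Compares pathogenic-variant calls between two platforms (by default
#' research exome calls versus clinical genetic-test results). Samples
#' flagged non-comparable in the clinical data (e.g. an ambiguous
#' historical record) are excluded from the comparable set by default and
#' reported separately. For each comparable sample, every variant called
#' on either platform is a compared pair; a pair is discordant when the
#' call (zygosity, or presence) differs. In era-aware mode a discordance
#' is marked `era_explained` when the knowledge-base assertion date for
#' the variant postdates the clinical test's `call_date` - the missed
#' allele was simply not on any panel at the time.
#'
#' @param cohort A `gs_cohort`.
#' @param kb A `variant_kb`; pathogenicity (at `as_of`) restricts the
#'   compared variants and supplies assertion dates for era explanations.
#' @param platform_a,platform_b Platforms to compare.
#' @param as_of Classification date.
#' @param era_aware Mark discordances explained by assertion dates.
#' @param include_noncomparable Include samples flagged non-comparable.
#' @return List of class `gs_concordance`: `n_comparable` /
#'   `n_concordant` (sample level), `n_pairs`, `pairs` (tibble),
#'   `discordances` (tibble with `era_explained`), `excluded_samples`.
#' @export
platform_concordance <- function(cohort, kb, platform_a = "WES",
                                 platform_b = "CLINICAL_PANEL",
                                 as_of = kb$snapshot_date, era_aware = FALSE,
                                 include_noncomparable = FALSE) {
  stopifnot(inherits(cohort, "gs_cohort"), inherits(kb, "variant_kb"))
  a <- filter(cohort$calls, .data$platform == platform_a)
  b <- filter(cohort$calls, .data$platform == platform_b)
  excluded <- b |> filter(!is.na(.data$comparable), !.data$comparable) |>
    pull(.data$sample_id) |> unique()
  if (!include_noncomparable) b <- filter(b, !.data$sample_id %in% excluded)
  shared <- intersect(unique(a$sample_id), unique(b$sample_id))
  if (length(shared) == 0L) {
    warn("no samples with calls on both platforms")
    return(structure(list(n_comparable = 0L, n_concordant = 0L, n_pairs = 0L,
                          pairs = tibble(), discordances = tibble(),
                          excluded_samples = excluded),
                     class = "gs_concordance"))
  }
  # restrict to knowledge-base pathogenic alleles: that is what the screen
  # (and any clinical panel) is asserting about
  path <- pathogenic_variants(kb, as_of = as_of)
  keep_keys <- path$variant_key
  a <- filter(a, .data$sample_id %in% shared, .data$variant_key %in% keep_keys)
  b <- filter(b, .data$sample_id %in% shared, .data$variant_key %in% keep_keys)
  # the clinical test date is a property of the sample's panel test, so a
  # variant the panel missed still inherits the sample's test date
  panel_dates <- b |> group_by(.data$sample_id) |>
    summarise(test_date = suppressWarnings(min(.data$call_date, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(test_date = as.Date(if_else(is.finite(.data$test_date),
                                       .data$test_date, as.Date(NA))))
  pairs <- full_join(
    a |> select("sample_id", "variant_key", "legacy_name", call_a = "zygosity"),
    b |> select("sample_id", "variant_key", "legacy_name", call_b = "zygosity"),
    by = c("sample_id", "variant_key"),
    suffix = c("", "_b")
  ) |>
    left_join(panel_dates, by = "sample_id") |>
    mutate(
      legacy_name = dplyr::coalesce(.data$legacy_name, .data$legacy_name_b),
      call_a = dplyr::coalesce(.data$call_a, "ABSENT"),
      call_b = dplyr::coalesce(.data$call_b, "ABSENT"),
      concordant = .data$call_a == .data$call_b
    ) |>
    select("sample_id", "variant_key", "legacy_name", "call_a", "call_b",
           "concordant", "test_date")
  disc <- filter(pairs, !.data$concordant)
  if (nrow(disc) > 0L) {
    asserted <- kb$assertions |>
      filter(!is.na(.data$variant_key)) |>
      group_by(.data$variant_key) |>
      summarise(first_asserted = min(.data$asserted_date), .groups = "drop")
    disc <- disc |>
      left_join(asserted, by = "variant_key") |>
      mutate(era_explained = era_aware & !is.na(.data$test_date) &
               !is.na(.data$first_asserted) & .data$first_asserted > .data$test_date)
  } else {
    disc$era_explained <- logical()
  }
  per_sample <- pairs |> group_by(.data$sample_id) |>
    summarise(ok = all(.data$concordant), .groups = "drop")
  structure(list(
    n_comparable = length(shared),
    n_concordant = sum(per_sample$ok),
    n_pairs = nrow(pairs),
    pairs = pairs,
    discordances = disc,
    excluded_samples = excluded
  ), class = "gs_concordance")
}

#' @export
print.gs_concordance <- function(x, ...) {
  cat("<gs_concordance>", x$n_concordant, "of", x$n_comparable,
      "comparable samples fully concordant (", x$n_pairs, "variant pairs )\n")
  if (nrow(x$discordances) > 0L) print(x$discordances)
  if (length(x$excluded_samples) > 0L) {
    cat("excluded (non-comparable):", paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}
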