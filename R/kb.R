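#' Load the variant knowledge base
#'
#' Builds a dated knowledge base from two assertion tables: a CFTR2-style
#' expert-curation snapshot and a ClinVar-style submission snapshot. Every
#' row becomes one pathogenicity assertion; a variant may be asserted by
#' one source, both, or neither. Queries at a date `d` ignore assertions
#' whose `asserted_date` is after `d`, which is how era-restricted screens
#' (e.g. against a historical panel) are expressed.
#'
#' Expected columns (TSV header or data frame): `legacy_name`,
#' `cdna_name`, `protein_name`, `classification`, `asserted_date`
#' (ISO-8601, may be empty = "always known"); the ClinVar-style table adds
#' `review_stars` (0-4) and optionally `url`. Optional `chrom`, `pos`,
#' `ref`, `alt` columns attach genomic coordinates so calls can be matched
#' by normalized variant identity rather than by label.
#'
#' @param cftr2_table,clinvar_table Path to a TSV file or a data frame.
#' @param snapshot_date Date of the database snapshots (ISO string or Date).
#' @return An object of class `variant_kb`: a list with `assertions`
#'   (tibble) and `snapshot_date`. Duplicate `(variant, source)` rows and
#'   malformed HGVS cDNA names are hard errors.
#' @examples
#' kb <- kb_fixture()
#' dplyr::count(kb$assertions, source)
#' @export
load_kb <- function(cftr2_table, clinvar_table, snapshot_date) {
  snapshot_date <- as.Date(snapshot_date)
  if (is.na(snapshot_date)) abort("snapshot_date is not a parseable date")
  cftr2 <- read_assertions(cftr2_table, source = "CFTR2")
  clinvar <- read_assertions(clinvar_table, source = "ClinVar")
  assertions <- bind_rows(cftr2, clinvar)
  dup <- assertions |>
    count(.data$source, .data$legacy_name) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicate assertion for variant ", dup$legacy_name[[1L]],
                 " in ", dup$source[[1L]], " table"))
  }
  structure(list(assertions = assertions, snapshot_date = snapshot_date),
            class = "variant_kb")
}

# classification labels the screen rule understands; others load but are flagged
.kb_known_labels <- list(
  CFTR2 = c("CF causing", "Varying clinical consequence", "Non CF-causing"),
  ClinVar = c("Pathogenic", "Likely pathogenic", "Benign", "Likely benign",
              "Uncertain significance", "Conflicting interpretations")
)
.kb_pathogenic_labels <- list(
  CFTR2 = "CF causing",
  ClinVar = c("Pathogenic", "Likely pathogenic")
)
.kb_benign_labels <- list(
  CFTR2 = "Non CF-causing",
  ClinVar = c("Benign", "Likely benign")
)

# sentinel "earliest" date: assertions without a date are always in force
.kb_epoch <- as.Date("1000-01-01")

read_assertions <- function(x, source) {
  tab <- if (is.character(x) && length(x) == 1L) {
    readr::read_tsv(x, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    as_tibble(x) |> mutate(across(dplyr::everything(), as.character))
  }
  if (nrow(tab) == 0L) {
    return(tibble(
      source = character(), legacy_name = character(), cdna_name = character(),
      protein_name = character(), tract_modifier = character(),
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      variant_key = character(), classification = character(),
      review_stars = integer(), asserted_date = as.Date(character()),
      unknown_label = logical()
    ))
  }
  need <- c("legacy_name", "cdna_name", "protein_name", "classification")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    abort(paste0(source, " table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!grepl("^c\\.", tab$cdna_name))
  if (length(bad) > 0L) {
    abort(paste0("malformed HGVS cDNA name in ", source, " table, row ",
                 bad[[1L]], ": '", tab$cdna_name[[bad[[1L]]]], "'"))
  }
  out <- tibble(
    source = source,
    legacy_name = tab$legacy_name,
    cdna_name = tab$cdna_name,
    protein_name = if ("protein_name" %in% names(tab))
      dplyr::coalesce(tab$protein_name, "") else "",
    tract_modifier = if ("tract_modifier" %in% names(tab))
      dplyr::coalesce(tab$tract_modifier, "") else "",
    classification = tab$classification,
    review_stars = if ("review_stars" %in% names(tab))
      suppressWarnings(as.integer(tab$review_stars)) else NA_integer_,
    asserted_date = if ("asserted_date" %in% names(tab)) {
      d <- as.Date(dplyr::na_if(dplyr::coalesce(tab$asserted_date, ""), ""))
      dplyr::coalesce(d, .kb_epoch)
    } else {
      rep(.kb_epoch, nrow(tab))
    }
  )
  if (any(!is.na(out$review_stars) & (out$review_stars < 0L | out$review_stars > 4L))) {
    abort(paste0(source, " table has review_stars outside 0-4"))
  }
  out$unknown_label <- !(out$classification %in% .kb_known_labels[[source]])
  if (any(out$unknown_label)) {
    warn(paste0(source, " table: unrecognised classification label(s) kept verbatim: ",
                paste(unique(out$classification[out$unknown_label]), collapse = ", ")))
  }
  if (all(c("chrom", "pos", "ref", "alt") %in% names(tab))) {
    coords <- normalize_variants(tibble(
      chrom = tab$chrom, pos = as.integer(tab$pos), ref = tab$ref, alt = tab$alt
    ))
    out$chrom <- coords$chrom
    out$pos <- coords$pos
    out$ref <- coords$ref
    out$alt <- coords$alt
    out$variant_key <- coords$variant_key
  } else {
    out$chrom <- NA_character_
    out$pos <- NA_integer_
    out$ref <- NA_character_
    out$alt <- NA_character_
    out$variant_key <- NA_character_
  }
  out
}

#' @export
print.variant_kb <- function(x, ...) {
  cat("<variant_kb> snapshot", format(x$snapshot_date), "\n")
  print(count(x$assertions, .data$source, .data$classification))
  invisible(x)
}

#' Classify variants against the knowledge base
#'
#' The screen rule of the analysis: an allele is `PATHOGENIC` when the
#' CFTR2-style source calls it "CF causing" *or* the ClinVar-style source
#' calls it "Pathogenic"/"Likely pathogenic" (union rule; ClinVar review
#' stars are recorded but not used as a filter). It is `NOT_PATHOGENIC`
#' when at least one source asserts, none qualifies as causal, and at
#' least one assertion is benign/non-causing. It is `UNKNOWN` when no
#' source has a determinative assertion as of the query date (absent from
#' both sources, or only indeterminate labels such as "Varying clinical
#' consequence" or VUS). Assertions dated after `as_of` are ignored, so a
#' variant first asserted in 2013 is `UNKNOWN` when queried as of 2009.
#'
#' @param kb A `variant_kb` from [load_kb()].
#' @param variants Data frame of query alleles; matched by normalized
#'   `variant_key` when coordinates are available on both sides, else by
#'   `legacy_name`.
#' @param as_of Query date; defaults to the snapshot date.
#' @return `variants` with columns `call` (PATHOGENIC / NOT_PATHOGENIC /
#'   UNKNOWN), `cftr2_classification`, `clinvar_classification`,
#'   `clinvar_stars`.
#' @export
classify_variants <- function(kb, variants, as_of = kb$snapshot_date) {
  stopifnot(inherits(kb, "variant_kb"))
  as_of <- as.Date(as_of)
  if (is.na(as_of)) abort("as_of is not a parseable date")
  if (as_of > kb$snapshot_date) {
    abort("as_of is after the knowledge-base snapshot date")
  }
  variants <- as_tibble(variants)
  if (!"legacy_name" %in% names(variants)) variants$legacy_name <- NA_character_
  has_coords <- all(c("chrom", "pos", "ref", "alt") %in% names(variants))
  if (!"variant_key" %in% names(variants) && has_coords &&
      !anyNA(variants$pos) && !anyNA(variants$ref)) {
    variants <- normalize_variants(variants)
  }
  if (nrow(variants) == 0L) {
    return(dplyr::bind_cols(variants, tibble(
      call = character(), cftr2_classification = character(),
      clinvar_classification = character(), clinvar_stars = integer())))
  }
  act <- filter(kb$assertions, .data$asserted_date <= as_of)
  qkey <- if ("variant_key" %in% names(variants)) variants$variant_key
          else rep(NA_character_, nrow(variants))
  hit <- function(i) {
    by_key <- !is.na(qkey[[i]]) & !is.na(act$variant_key) & act$variant_key == qkey[[i]]
    by_name <- !is.na(variants$legacy_name[[i]]) & variants$legacy_name[[i]] != "" &
      act$legacy_name == variants$legacy_name[[i]]
    act[by_key | by_name, ]
  }
  res <- purrr::map(seq_len(nrow(variants)), function(i) {
    a <- hit(i)
    patho <- any(purrr::map2_lgl(a$source, a$classification,
                                 ~ .y %in% .kb_pathogenic_labels[[.x]]))
    benign <- any(purrr::map2_lgl(a$source, a$classification,
                                  ~ .y %in% .kb_benign_labels[[.x]]))
    call <- if (patho) "PATHOGENIC" else if (benign) "NOT_PATHOGENIC" else "UNKNOWN"
    cftr2 <- a$classification[a$source == "CFTR2"]
    clinvar <- a$classification[a$source == "ClinVar"]
    stars <- a$review_stars[a$source == "ClinVar"]
    tibble(
      call = call,
      cftr2_classification = if (length(cftr2)) cftr2[[1L]] else NA_character_,
      clinvar_classification = if (length(clinvar)) clinvar[[1L]] else NA_character_,
      clinvar_stars = if (length(stars)) stars[[1L]] else NA_integer_
    )
  })
  dplyr::bind_cols(variants, bind_rows(res))
}

#' Classify one variant
#'
#' Scalar convenience wrapper around [classify_variants()].
#'
#' @inheritParams classify_variants
#' @param variant One-row data frame, or a legacy name string.
#' @return Length-1 character: `"PATHOGENIC"`, `"NOT_PATHOGENIC"` or
#'   `"UNKNOWN"`.
#' @examples
#' classify_variant(kb_fixture(), "F508del")
#' @export
classify_variant <- function(kb, variant, as_of = kb$snapshot_date) {
  if (is.character(variant)) variant <- tibble(legacy_name = variant)
  classify_variants(kb, variant, as_of = as_of)$call
}

#' Pathogenic allele set at a date
#'
#' @param kb A `variant_kb`.
#' @param as_of Query date (default: snapshot date).
#' @return Tibble of distinct alleles classified PATHOGENIC as of `as_of`,
#'   with `legacy_name` and (where available) coordinates.
#' @export
pathogenic_variants <- function(kb, as_of = kb$snapshot_date) {
  q <- kb$assertions |>
    distinct(.data$legacy_name, .keep_all = TRUE) |>
    select("legacy_name", "cdna_name", "protein_name", "chrom", "pos",
           "ref", "alt", "variant_key")
  cls <- classify_variants(kb, select(q, "legacy_name"), as_of = as_of)
  q |>
    mutate(call = cls$call) |>
    filter(.data$call == "PATHOGENIC") |>
    select(-"call")
}
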