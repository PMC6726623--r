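#' Build a variant allele table
#'
#' A variant allele is one normalized coding change: genomic coordinates
#' plus its HGVS-style cDNA and protein names and a short legacy label
#' (e.g. `F508del`). The `(chrom, pos, ref, alt)` tuple after
#' normalization is the identity key; `legacy_name` must be unique within
#' a knowledge base.
#'
#' @param chrom Chromosome label (character).
#' @param pos 1-based genomic position (integer-ish, `>= 1`).
#' @param ref,alt Reference / alternate allele strings (`ref != alt`).
#' @param cdna_name HGVS-style coding name, e.g. `"c.1521_1523delCTT"`.
#' @param protein_name HGVS-style protein name, or `""` for intronic.
#' @param legacy_name Short label, e.g. `"F508del"`.
#' @param tract_modifier Optional poly-T/TG annotation (e.g. `"T5/TG11"`),
#'   carried as a string and ignored by classification.
#' @return A tibble with one row per allele, normalized (left-aligned,
#'   minimal representation) and carrying a `variant_key` column.
#' @examples
#' variant_tbl("7", 117101520, "ACTT", "A",
#'             "c.1521_1523delCTT", "p.Phe508del", "F508del")
#' @export
variant_tbl <- function(chrom, pos, ref, alt, cdna_name = "", protein_name = "",
                        legacy_name = "", tract_modifier = "") {
  v <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    cdna_name = as.character(cdna_name), protein_name = as.character(protein_name),
    legacy_name = as.character(legacy_name),
    tract_modifier = as.character(tract_modifier)
  )
  normalize_variants(v)
}

#' Normalize variant representations
#'
#' Applies the VCF convention for a minimal, left-aligned representation:
#' the common suffix of `ref` and `alt` is trimmed first, then the common
#' prefix (advancing `pos`), always retaining at least one base on each
#' side so alleles stay anchored. Adds/refreshes a `variant_key` column
#' (`chrom:pos:ref:alt`) used as the identity key throughout the package.
#'
#' @param v A data frame with `chrom`, `pos`, `ref`, `alt` columns.
#' @return `v` as a tibble with normalized coordinates and a `variant_key`.
#' @export
normalize_variants <- function(v) {
  v <- as_tibble(v)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  if (any(v$ref == v$alt)) {
    abort("ref and alt must differ for every variant")
  }
  if (any(v$pos < 1L)) abort("pos must be >= 1")
  norm <- purrr::pmap(list(v$pos, v$ref, v$alt), normalize_one)
  v$pos <- purrr::map_int(norm, 1L)
  v$ref <- purrr::map_chr(norm, 2L)
  v$alt <- purrr::map_chr(norm, 3L)
  v$variant_key <- variant_key(v)
  v
}

# trim common suffix then common prefix, keeping >= 1 base per allele
normalize_one <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(as.integer(pos), paste(r, collapse = ""), paste(a, collapse = ""))
}

#' Variant identity key
#'
#' @param v Data frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Select the annotation transcript
#'
#' Transcript selection rule used to anchor cDNA/protein names: keep
#' transcripts that carry a Locus Reference Genome (LRG) annotation and
#' have annotated start and stop codons, then take the longest coding
#' sequence. Ties are broken by the lexicographically smallest accession,
#' so the choice is deterministic and independent of input order.
#'
#' @param candidates Data frame with columns `transcript_id`, `has_lrg`
#'   (logical), `cds_length` (integer), `has_start_stop` (logical).
#' @return The selected transcript accession (length-1 character).
#' @examples
#' select_transcript(tibble::tibble(
#'   transcript_id = c("NM_000492.3", "NM_999.1"),
#'   has_lrg = c(TRUE, TRUE), cds_length = c(4443L, 300L),
#'   has_start_stop = c(TRUE, FALSE)))
#' @export
select_transcript <- function(candidates) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0L) abort("no candidate transcripts supplied")
  stopifnot(all(c("transcript_id", "has_lrg", "cds_length", "has_start_stop") %in%
                  names(candidates)))
  if (any(candidates$has_start_stop & candidates$cds_length <= 0L)) {
    abort("cds_length must be positive when start/stop codons are annotated")
  }
  eligible <- dplyr::filter(candidates, .data$has_lrg, .data$has_start_stop)
  if (nrow(eligible) == 0L) abort("no eligible transcript")
  eligible <- dplyr::arrange(eligible, dplyr::desc(.data$cds_length),
                             .data$transcript_id)
  eligible$transcript_id[[1L]]
}
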