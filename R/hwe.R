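# conditional distribution of the heterozygote count given n individuals and
# n_a copies of the rarer allele, as plain vectors (log-gamma closed form):
# P(h | n, n_a) proportional to 2^h * n! / (n_aa! * h! * n_bb!)
hwe_dist <- function(n, n_a) {
  n_a <- min(n_a, 2L * n - n_a)
  h <- seq(n_a %% 2L, n_a, by = 2L)
  hom_minor <- (n_a - h) / 2
  hom_major <- n - h - hom_minor
  log_num <- h * log(2) + lgamma(n + 1) -
    (lgamma(hom_minor + 1) + lgamma(h + 1) + lgamma(hom_major + 1))
  w <- exp(log_num - max(log_num))
  list(n_het = as.integer(h), prob = w / sum(w))
}

#' Conditional distribution of heterozygote counts under Hardy-Weinberg
#'
#' Given `n` diploid individuals and `n_a` copies of the rarer allele, the
#' exact Hardy-Weinberg test conditions on the allele counts: the number
#' of heterozygotes `h` then ranges over values of the same parity as
#' `n_a`, with probability proportional to
#' `2^h * n! / (((n_a-h)/2)! * h! * ((n_b-h)/2)!)` where `n_b = 2n - n_a`.
#' Computed in log space and normalized.
#'
#' @param n Number of individuals (`> 0`).
#' @param n_a Count of the rarer allele (values up to `2n` are folded to
#'   the minor allele automatically).
#' @return Tibble with `n_het` and `prob` for every attainable
#'   heterozygote count.
#' @export
hwe_het_distribution <- function(n, n_a) {
  stopifnot(n > 0L, n_a >= 0L, n_a <= 2L * n)
  d <- hwe_dist(n, n_a)
  tibble(n_het = d$n_het, prob = d$prob)
}

#' Exact Hardy-Weinberg p-values for every heterozygote count
#'
#' The two-sided exact test p-value for an observed heterozygote count is
#' the summed probability of all counts whose conditional probability does
#' not exceed the observed one. This vectorized form returns the p-value
#' at every attainable count at once (used by exhaustive QC sweeps);
#' [hwe_exact_test()] is the single-marker wrapper.
#'
#' @inheritParams hwe_het_distribution
#' @return Tibble: `n_het`, `prob`, `p_value`.
#' @export
hwe_exact_pvalues <- function(n, n_a) {
  stopifnot(n > 0L, n_a >= 0L, n_a <= 2L * n)
  d <- hwe_dist(n, n_a)
  ord <- order(d$prob)
  ps <- d$prob[ord]
  cum <- cumsum(ps)
  # include ties up to a relative tolerance against floating-point noise
  idx <- findInterval(ps * (1 + 1e-10), ps)
  p <- numeric(length(ps))
  p[ord] <- pmin(cum[idx], 1)
  tibble(n_het = d$n_het, prob = d$prob, p_value = p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts. This is
#' the standard marker-QC test applied with a `p > 1e-06` threshold;
#' monomorphic markers give `p = 1`.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative,
#'   total `> 0`).
#' @return Exact p-value in `(0, 1]`.
#' @examples
#' hwe_exact_test(57, 36, 7)
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) abort("genotype counts must be non-negative")
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero")
  n_a <- 2L * n_hom_alt + n_het
  pv <- hwe_exact_pvalues(n, n_a)
  p <- pv$p_value[pv$n_het == n_het]
  if (length(p) != 1L) {
    abort("heterozygote count is inconsistent with the allele counts")
  }
  p
}

#' Marker QC from genotype counts
#'
#' Applies the array-marker quality thresholds: genotype call rate
#' `> 0.98`, exact Hardy-Weinberg `p > 1e-06`, and minor-allele count
#' `>= 2`. Missing genotypes count against the call-rate denominator but
#' are excluded from the genotype counts.
#'
#' @param n_hom_ref,n_het,n_hom_alt Called genotype counts.
#' @param n_missing Number of no-call genotypes.
#' @return One-row tibble: `call_rate`, `hwe_p`, `minor_allele_count`,
#'   `passed`.
#' @export
marker_qc_counts <- function(n_hom_ref, n_het, n_hom_alt, n_missing = 0L) {
  n_called <- n_hom_ref + n_het + n_hom_alt
  call_rate <- n_called / (n_called + n_missing)
  hwe_p <- if (n_called > 0L) hwe_exact_test(n_hom_ref, n_het, n_hom_alt) else NA_real_
  n_a <- 2L * n_hom_alt + n_het
  mac <- min(n_a, 2L * n_called - n_a)
  tibble(
    call_rate = call_rate, hwe_p = hwe_p, minor_allele_count = as.integer(mac),
    passed = !is.na(hwe_p) & call_rate > 0.98 & hwe_p > 1e-06 & mac >= 2L
  )
}

#' Array-marker quality control over a cohort
#'
#' @param cohort A `gs_cohort`.
#' @param platform Platform whose calls are QCed (default `"ARRAY"`).
#' @return Tibble with one row per assayed variant: `variant_key`,
#'   `legacy_name`, genotype counts, `call_rate`, `hwe_p`,
#'   `minor_allele_count`, `passed`.
#' @export
marker_qc <- function(cohort, platform = "ARRAY") {
  stopifnot(inherits(cohort, "gs_cohort"))
  n <- cohort_size(cohort)
  calls <- filter(cohort$calls, .data$platform == .env$platform)
  nc <- filter(cohort$no_calls, .data$platform == .env$platform)
  per <- cohort$variants |>
    select("variant_key", "legacy_name") |>
    left_join(calls |> count(.data$variant_key, .data$zygosity) |>
                tidyr::pivot_wider(names_from = "zygosity", values_from = "n",
                                   values_fill = 0L),
              by = "variant_key") |>
    left_join(nc |> count(.data$variant_key, name = "n_missing"),
              by = "variant_key")
  for (col in c("HET", "HOM_ALT", "n_missing")) {
    if (!col %in% names(per)) per[[col]] <- 0L
    per[[col]] <- dplyr::coalesce(per[[col]], 0L)
  }
  qc <- purrr::pmap(list(per$HET, per$HOM_ALT, per$n_missing),
                    function(het, hom, miss) {
                      marker_qc_counts(n - miss - het - hom, het, hom, miss)
                    })
  dplyr::bind_cols(select(per, "variant_key", "legacy_name",
                          n_het = "HET", n_hom_alt = "HOM_ALT", "n_missing"),
                   bind_rows(qc))
}
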