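#' Simulation parameters for a recessive-disease cohort
#'
#' Defaults encode the population genetics of cystic fibrosis in a
#' northern-European-background cohort: a total pathogenic carrier
#' frequency of 1 in 28 (rare-allele arithmetic: `q = 1/56`, affected
#' fraction `q^2 = 1/3136`), one dominant allele (F508del) carrying 70% of
#' pathogenic alleles with the remainder split over 11 minor alleles,
#' and essentially complete penetrance of the bi-allelic genotype.
#' EHR phenotyping is imperfect: a true case has confirmable chart facts
#' with probability `chart_completeness` (its complement reproduces the
#' "potential false positive" mechanism - insufficient evidence for,
#' rather than against, the diagnosis), carries a CF diagnosis code with
#' probability `code_sensitivity`, and non-cases carry one at rate
#' `code_fpr`. `kb_completeness` is the probability that each truly
#' causal allele is present in the knowledge base; values below 1 create
#' screen false negatives whose missing allele is simply unasserted.
#'
#' @param n_individuals Cohort size.
#' @param carrier_frequency Total pathogenic-carrier frequency (HWE).
#' @param pathogenic_allele_freqs Optional named frequency map
#'   (variant -> per-haplotype frequency). Must be HWE-consistent with
#'   `carrier_frequency` (checked; inconsistency is a hard error).
#' @param f508del_share Share of pathogenic alleles on the dominant
#'   allele when the default spectrum is built.
#' @param n_other_alleles Number of minor pathogenic alleles in the
#'   default spectrum.
#' @param penetrance P(bi-allelic individual is a true case).
#' @param chart_completeness P(true case has confirmable chart facts).
#' @param code_sensitivity P(true case carries a CF ICD-10 code).
#' @param code_fpr P(non-case carries a CF ICD-10 code).
#' @param kb_completeness P(causal allele present in the knowledge base).
#' @param panel_variants,panel_date Optional era-limited clinical panel:
#'   legacy names covered and the panel's test date.
#' @param array_marker_subset Legacy names genotyped on the array
#'   (default: all).
#' @param array_missing_rate Per-genotype no-call rate on the array.
#' @param genotype_error_rate Per-call dropout rate for exome calls.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_individuals = 50778, carrier_frequency = 1 / 28,
                       pathogenic_allele_freqs = NULL, f508del_share = 0.70,
                       n_other_alleles = 11, penetrance = 1.0,
                       chart_completeness = 0.875, code_sensitivity = 0.95,
                       code_fpr = 1.2e-4, kb_completeness = 1.0,
                       panel_variants = NULL, panel_date = NULL,
                       array_marker_subset = NULL, array_missing_rate = 0.005,
                       genotype_error_rate = 0, seed = 1L) {
  probs <- c(penetrance = penetrance, chart_completeness = chart_completeness,
             code_sensitivity = code_sensitivity, code_fpr = code_fpr,
             kb_completeness = kb_completeness,
             array_missing_rate = array_missing_rate,
             genotype_error_rate = genotype_error_rate)
  if (any(probs < 0 | probs > 1)) {
    abort(paste0("probability parameter outside [0, 1]: ",
                 names(probs)[which(probs < 0 | probs > 1)][[1L]]))
  }
  if (carrier_frequency <= 0 || carrier_frequency >= 0.5) {
    abort("carrier_frequency must be in (0, 0.5)")
  }
  if (is.null(pathogenic_allele_freqs)) {
    # classical rare-allele arithmetic: carrier frequency ~ 2q, so a carrier
    # rate of 1/28 gives q = 1/56 and an affected fraction q^2 = 1/3136,
    # the familiar 1-in-3200 (0.03%) prevalence figure
    q <- carrier_frequency / 2
    minor <- setNames(rep(q * (1 - f508del_share) / n_other_alleles, n_other_alleles),
                      sprintf("PVAR%02d", seq_len(n_other_alleles)))
    pathogenic_allele_freqs <- c(F508del = q * f508del_share, minor)
  } else {
    q <- sum(pathogenic_allele_freqs)
    implied <- 2 * q * (1 - q)
    if (abs(implied - carrier_frequency) > 0.05 * carrier_frequency) {
      abort(sprintf(paste0("pathogenic_allele_freqs imply a carrier frequency of ",
                           "%.5f, inconsistent with carrier_frequency = %.5f"),
                    implied, carrier_frequency))
    }
  }
  if (any(pathogenic_allele_freqs <= 0)) abort("allele frequencies must be positive")
  structure(list(
    n_individuals = as.integer(n_individuals),
    carrier_frequency = carrier_frequency,
    pathogenic_allele_freqs = pathogenic_allele_freqs,
    penetrance = penetrance, chart_completeness = chart_completeness,
    code_sensitivity = code_sensitivity, code_fpr = code_fpr,
    kb_completeness = kb_completeness,
    panel_variants = panel_variants, panel_date = panel_date,
    array_marker_subset = array_marker_subset,
    array_missing_rate = array_missing_rate,
    genotype_error_rate = genotype_error_rate,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate a screening cohort
#'
#' Draws two haplotypes per individual i.i.d. from the pathogenic
#' frequency spectrum (random mating, Hardy-Weinberg; cis double
#' heterozygotes are not simulated), applies penetrance to bi-allelic
#' genotypes to define true cases, and emits the full input bundle the
#' pipeline consumes - genotype calls, manifest, diagnosis codes, chart
#' facts, a knowledge base (possibly incomplete), and a hidden truth
#' table. Fully reproducible per seed.
#'
#' Chart facts for a true case are confirmable (diagnostic sweat chloride,
#' CF-clinic care, pancreatic supplementation, documented diagnosis) with
#' probability `chart_completeness`, otherwise the chart row is
#' uninformative, which adjudicates as `INSUFFICIENT`. Every individual
#' who could be queued (bi-allelic genotype or code positive) gets a
#' chart row.
#'
#' @param params A [sim_params()] object.
#' @param seed Overrides `params$seed` when given.
#' @return A `gs_simulation`: list with `cohort` (a `gs_cohort`), `kb`
#'   (a `variant_kb`), `truth` (tibble: `sample_id`, `is_case`,
#'   `causal_alleles`, `n_pathogenic_alleles`) and `params`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_individuals = 2000, seed = 7))
#' sum(sim$truth$is_case)
#' @export
simulate_cohort <- function(params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  n <- params$n_individuals
  freqs <- params$pathogenic_allele_freqs
  k <- length(freqs)
  sample_ids <- sprintf("S%07d", seq_len(n))

  # haplotypes: 0 = reference, 1..k = pathogenic allele index
  p <- c(1 - sum(freqs), unname(freqs))
  hap1 <- sample.int(k + 1L, n, replace = TRUE, prob = p) - 1L
  hap2 <- sample.int(k + 1L, n, replace = TRUE, prob = p) - 1L

  carrier_idx <- which(hap1 > 0L | hap2 > 0L)
  i1 <- carrier_idx[hap1[carrier_idx] > 0L]
  i2 <- carrier_idx[hap2[carrier_idx] > 0L & hap2[carrier_idx] != hap1[carrier_idx]]
  calls <- tibble(
    sample_id = sample_ids[c(i1, i2)],
    allele_idx = c(hap1[i1], hap2[i2]),
    zygosity = c(if_else(hap1[i1] == hap2[i1], "HOM_ALT", "HET"),
                 rep("HET", length(i2)))
  ) |> arrange(.data$sample_id, .data$allele_idx)

  variants <- sim_variant_table(names(freqs))
  calls <- calls |>
    mutate(legacy_name = names(freqs)[.data$allele_idx],
           variant_key = variants$variant_key[.data$allele_idx],
           platform = "WES", call_date = as.Date(NA), comparable = NA) |>
    select("sample_id", "variant_key", "legacy_name", "zygosity",
           "platform", "call_date", "comparable")
  if (params$genotype_error_rate > 0 && nrow(calls) > 0L) {
    calls <- calls[runif(nrow(calls)) >= params$genotype_error_rate, ]
  }

  biallelic <- hap1 > 0L & hap2 > 0L
  is_case <- biallelic & rbinom(n, 1L, params$penetrance) == 1L

  # knowledge base: each simulated causal allele asserted independently
  in_kb <- runif(k) < params$kb_completeness
  kb <- sim_kb(variants, in_kb)

  # diagnosis codes
  code_draw <- runif(n)
  has_code <- (is_case & code_draw < params$code_sensitivity) |
    (!is_case & code_draw < params$code_fpr)
  codes <- tibble(sample_id = sample_ids[has_code],
                  icd10_code = if_else(is_case[has_code], "E84.0", "E84.9"))

  # chart facts for everyone who could reach the review queue
  chart_complete <- is_case & runif(n) < params$chart_completeness
  needs_chart <- which(biallelic | has_code)
  sweat_vals <- round(runif(n, 75, 110))
  chart <- tibble(
    sample_id = sample_ids[needs_chart],
    sweat_values = if_else(chart_complete[needs_chart],
                           as.character(sweat_vals[needs_chart]), "-"),
    clinical_variants = "-",
    bronchiectasis = "unknown",
    pancreatic_supplement = if_else(chart_complete[needs_chart], "yes", "unknown"),
    respiratory_pseudomonas = "unknown",
    cf_clinic_care = if_else(chart_complete[needs_chart], "yes", "no"),
    cf_dx_in_ehr = if_else(chart_complete[needs_chart], "yes", "no")
  )

  # array platform: confirmatory genotypes with missingness
  array_subset <- params$array_marker_subset
  if (is.null(array_subset)) array_subset <- names(freqs)
  array_calls <- calls |>
    filter(.data$legacy_name %in% array_subset) |>
    mutate(platform = "ARRAY")
  no_calls <- empty_no_calls()
  if (params$array_missing_rate > 0) {
    sub_keys <- variants$variant_key[variants$legacy_name %in% array_subset]
    nc_list <- lapply(sub_keys, function(key) {
      m <- rbinom(1L, n, params$array_missing_rate)
      if (m == 0L) return(NULL)
      tibble(sample_id = sample_ids[sample.int(n, m)],
             variant_key = key, platform = "ARRAY")
    })
    nc_list <- nc_list[!vapply(nc_list, is.null, logical(1))]
    if (length(nc_list)) no_calls <- bind_rows(nc_list)
    # a no-call suppresses any stored array call for that genotype
    array_calls <- anti_join(array_calls, no_calls,
                             by = c("sample_id", "variant_key"))
  }

  # optional era-limited clinical panel for chart-complete cases
  clinical_calls <- empty_calls()
  if (!is.null(params$panel_variants)) {
    clinical_calls <- calls |>
      filter(.data$sample_id %in% sample_ids[chart_complete],
             .data$legacy_name %in% params$panel_variants) |>
      mutate(platform = "CLINICAL_PANEL",
             call_date = as.Date(params$panel_date), comparable = TRUE)
  }

  samples <- tibble(
    sample_id = sample_ids,
    age_years = round(runif(n, 1, 90)),
    sex = if_else(runif(n) < 0.5, "F", "M")
  )
  cohort <- new_cohort(samples = samples, variants = variants,
                       calls = bind_rows(calls, array_calls, clinical_calls),
                       codes = codes, chart = chart, no_calls = no_calls)
  causal <- rep("", n)
  causal[carrier_idx] <- vapply(carrier_idx, function(i) {
    a <- c(hap1[[i]], hap2[[i]])
    paste(names(freqs)[a[a > 0L]], collapse = ";")
  }, character(1))
  truth <- tibble(sample_id = sample_ids, is_case = is_case,
                  causal_alleles = causal,
                  n_pathogenic_alleles = (hap1 > 0L) + (hap2 > 0L))
  structure(list(cohort = cohort, kb = kb, truth = truth, params = params),
            class = "gs_simulation")
}

# synthetic single-gene variant table: one SNV per simulated allele,
# except the dominant allele which is the canonical 3-bp deletion
sim_variant_table <- function(legacy_names) {
  k <- length(legacy_names)
  pos <- 117100000L + 1000L * seq_len(k)
  ref <- rep("C", k)
  alt <- rep("T", k)
  del <- legacy_names == "F508del"
  ref[del] <- "ACTT"
  alt[del] <- "A"
  variant_tbl(chrom = rep("7", k), pos = pos, ref = ref, alt = alt,
              cdna_name = sprintf("c.%d>sim", seq_len(k)),
              protein_name = "", legacy_name = legacy_names)
}

sim_kb <- function(variants, in_kb) {
  asserted <- variants[in_kb, , drop = FALSE]
  tab <- tibble(
    legacy_name = asserted$legacy_name,
    cdna_name = asserted$cdna_name,
    protein_name = asserted$protein_name,
    classification = "CF causing",
    asserted_date = "",
    chrom = asserted$chrom, pos = asserted$pos,
    ref = asserted$ref, alt = asserted$alt
  )
  clinvar <- tab |>
    mutate(classification = "Pathogenic", review_stars = "4")
  load_kb(tab, clinvar, snapshot_date = Sys.Date())
}

#' @export
print.gs_simulation <- function(x, ...) {
  cat("<gs_simulation> n =", cohort_size(x$cohort), ";",
      sum(x$truth$is_case), "true cases; seed", x$params$seed, "\n")
  invisible(x)
}

#' Analytic expectations for a simulated screen
#'
#' Closed-form companions used in parameter-recovery tests:
#' * prevalence (percent) `= Q^2 * penetrance * 100` with
#'   `Q = sum(pathogenic_allele_freqs)`;
#' * sensitivity (percent): with per-variant knowledge-base inclusion at
#'   rate `k`, a case screens positive when both allele *types* are
#'   asserted, so `E[sens] = k^2 (1 - h) + k h` where
#'   `h = sum(f_i^2) / Q^2` is the probability a bi-allelic genotype is
#'   homozygous; `k^2` is the compound-heterozygote limit;
#' * pipeline sensitivity (percent): the measured `tp/(tp+fn)` of the
#'   full pipeline additionally conditions on a missed case being
#'   captured by its diagnosis codes, `s / (s + (1-s) * code_sensitivity)`
#'   (chart completeness cancels because it gates TP and FN alike);
#' * PPV (percent) `= penetrance * chart_completeness` - a screen
#'   positive is a true positive when it is a real case (penetrance) with
#'   confirmable chart facts (chart completeness).
#'
#' These are expectations under the generator's assumptions (random
#' mating, independent phenotyping draws), not guarantees about any real
#' cohort.
#'
#' @param params A [sim_params()] object.
#' @return Tibble: `statistic`, `expected` (percent scale).
#' @export
expected_stats <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  f <- params$pathogenic_allele_freqs
  q <- sum(f)
  h <- sum(f^2) / q^2
  k <- params$kb_completeness
  s <- k^2 * (1 - h) + k * h
  tibble(
    statistic = c("prevalence", "sensitivity", "pipeline_sensitivity", "ppv"),
    expected = 100 * c(
      q^2 * params$penetrance,
      s,
      s / (s + (1 - s) * params$code_sensitivity),
      params$penetrance * params$chart_completeness
    )
  )
}
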