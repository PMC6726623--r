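kb <- kb_fixture()

test_that("single-individual screening reproduces the case-series calls", {
  # homozygote for the major pathogenic allele
  hom <- screen_individual(
    tibble::tibble(legacy_name = "F508del", zygosity = "HOM_ALT"), kb)
  expect_equal(hom$status, "BIALLELIC_POSITIVE")
  expect_equal(hom$n_pathogenic_alleles, 2L)
  # compound heterozygote of two asserted pathogenic alleles
  cpd <- screen_individual(
    tibble::tibble(legacy_name = c("F508del", "Q39X"),
                   zygosity = c("HET", "HET")), kb)
  expect_equal(cpd$status, "BIALLELIC_POSITIVE")
  # second allele unknown to the knowledge base: carrier, not positive
  fn_like <- screen_individual(
    tibble::tibble(legacy_name = c("F508del", "R1239S"),
                   zygosity = c("HET", "HET")), kb)
  expect_equal(fn_like$status, "CARRIER")
  # second allele asserted benign: carrier
  benign <- screen_individual(
    tibble::tibble(legacy_name = c("F508del", "S1235R"),
                   zygosity = c("HET", "HET")), kb)
  expect_equal(benign$status, "CARRIER")
  # no stored calls at all
  none <- screen_individual(
    tibble::tibble(legacy_name = character(), zygosity = character()), kb)
  expect_equal(none$status, "NEGATIVE")
})

test_that("three pathogenic alleles still map to bi-allelic positive", {
  tri <- screen_individual(
    tibble::tibble(legacy_name = c("F508del", "G542X", "G551D"),
                   zygosity = "HET"), kb)
  expect_equal(tri$status, "BIALLELIC_POSITIVE")
  expect_equal(tri$n_pathogenic_alleles, 3L)
  expect_match(tri$pathogenic_alleles, "F508del")
  expect_match(tri$pathogenic_alleles, "G551D")
})

test_that("screening ignores call order and duplicated identical calls", {
  calls <- tibble::tibble(legacy_name = c("F508del", "G542X"),
                          zygosity = c("HET", "HET"))
  fwd <- screen_individual(calls, kb)
  rev <- screen_individual(calls[2:1, ], kb)
  dup <- screen_individual(dplyr::bind_rows(calls, calls[1, ]), kb)
  expect_equal(fwd$status, rev$status)
  expect_equal(fwd$n_pathogenic_alleles, rev$n_pathogenic_alleles)
  expect_equal(fwd, dup)
})

test_that("non-pathogenic calls never influence the status", {
  tkb <- toy_kb()
  with_noise <- toy_cohort(list(A = c(VP1 = 1, VB = 2, VU = 1),
                                B = c(VB = 2, VU = 2),
                                C = c(VP1 = 1, VP2 = 1, VB = 1)))
  without <- toy_cohort(list(A = c(VP1 = 1), B = numeric(),
                             C = c(VP1 = 1, VP2 = 1)))
  s1 <- screen_cohort(with_noise, tkb)
  s2 <- screen_cohort(without, tkb)
  expect_equal(s1$status, s2$status)
  expect_equal(s1$status, c("CARRIER", "NEGATIVE", "BIALLELIC_POSITIVE"))
})

test_that("statuses partition every cohort", {
  cohort <- fixture_small(300)
  s <- screen_cohort(cohort, kb)
  sm <- screen_summary(s)
  expect_equal(sm$n_positive + sm$n_carrier + sm$n_negative, sm$n)
  expect_equal(sm$n, cohort_size(cohort))
  empty <- new_cohort(tibble::tibble(sample_id = character(),
                                     age_years = double(), sex = character()))
  se <- screen_summary(screen_cohort(empty, kb))
  expect_equal(unlist(se), c(n_positive = 0L, n_carrier = 0L,
                             n_negative = 0L, n = 0L))
})

test_that("screen status matches the exhaustive truth-table oracle", {
  tkb <- toy_kb()
  path_set <- c(VP1 = TRUE, VP2 = TRUE, VB = FALSE, VU = FALSE)
  doses_grid <- expand.grid(VP1 = 0:2, VP2 = 0:2, VB = 0:2, VU = 0:2)
  for (i in seq_len(nrow(doses_grid))) {
    doses <- unlist(doses_grid[i, ])
    genotypes <- tibble::tibble(
      legacy_name = names(doses)[doses > 0],
      zygosity = ifelse(doses[doses > 0] == 2, "HOM_ALT", "HET"))
    got <- screen_individual(genotypes, tkb)$status
    expect_equal(got, oracle_screen_status(doses, path_set[names(doses)]),
                 info = paste(doses, collapse = "/"))
  }
})

test_that("cohort screening and era restriction behave on the case series", {
  cohort <- fixture_small(300)
  s <- screen_cohort(cohort, kb)
  expect_equal(screen_summary(s)$n_positive, 24L)
  # restricted to a 2009 knowledge state the latest-asserted allele drops out
  s09 <- screen_cohort(cohort, kb, as_of = "2009-01-01")
  expect_equal(screen_summary(s09)$n_positive, 23L)
  lost <- dplyr::setdiff(
    dplyr::filter(as_tibble(s), status == "BIALLELIC_POSITIVE")$sample_id,
    dplyr::filter(as_tibble(s09), status == "BIALLELIC_POSITIVE")$sample_id)
  expect_equal(lost, "CASE26")
})

test_that("allele accounting splits compound-het and homozygous copies", {
  tkb <- toy_kb()
  solo <- toy_cohort(list(A = c(VP1 = 2)))
  acc <- allele_accounting(solo)
  expect_equal(acc$n_alleles_compound_het, 0L)
  expect_equal(acc$n_alleles_homozygous, 2L)
  expect_equal(acc$percent, 100)
  mixed <- toy_cohort(list(A = c(VP1 = 2), B = c(VP1 = 1, VP2 = 1)))
  acc2 <- allele_accounting(mixed)
  vp1 <- dplyr::filter(acc2, legacy_name == "VP1")
  expect_equal(vp1$n_alleles_total, 3L)
  expect_equal(sum(acc2$n_alleles_total), 4L)
})

test_that("platform concordance flags zygosity and presence mismatches", {
  tkb <- toy_kb()
  cohort <- toy_cohort(list(A = c(VP1 = 1, VP2 = 1), B = c(VP1 = 2)))
  clin <- cohort$calls |>
    dplyr::mutate(platform = "CLINICAL_PANEL",
                  call_date = as.Date("2016-01-01"), comparable = TRUE)
  cohort$calls <- dplyr::bind_rows(cohort$calls, clin)
  conc <- platform_concordance(cohort, tkb)
  expect_equal(conc$n_comparable, 2L)
  expect_equal(conc$n_concordant, 2L)
  expect_equal(nrow(conc$discordances), 0L)
  # drop one of A's clinical calls: now a presence discordance for A
  cohort2 <- cohort
  cohort2$calls <- dplyr::filter(
    cohort2$calls,
    !(platform == "CLINICAL_PANEL" & sample_id == "A" & legacy_name == "VP2"))
  conc2 <- platform_concordance(cohort2, tkb)
  expect_equal(conc2$n_concordant, conc2$n_comparable - 1L)
  expect_equal(unname(conc2$discordances$call_b), "ABSENT")
})

test_that("concordance warns when no samples are comparable", {
  tkb <- toy_kb()
  cohort <- toy_cohort(list(A = c(VP1 = 1)))
  expect_warning(conc <- platform_concordance(cohort, tkb), "no samples")
  expect_equal(conc$n_comparable, 0L)
})
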