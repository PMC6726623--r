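kb <- kb_fixture()
fixture_chart <- read_chart(system.file("extdata", "cohort_chart.tsv",
                                        package = "genoscreen"))

chart_row <- function(id) dplyr::filter(fixture_chart, sample_id == id)

test_that("the rule engine reproduces the reviewed case labels", {
  # diagnostic sweat plus bi-allelic genetics
  lab1 <- confirm_diagnosis(chart_row("CASE01"), "BIALLELIC_POSITIVE", kb,
                            has_cf_code = TRUE)
  expect_equal(lab1$label, "CF_CONFIRMED")
  expect_match(lab1$basis, "sweat_gt60\\+biallelic_genetics")
  # no sweat testing: bi-allelic genetics plus clinical features
  lab17 <- confirm_diagnosis(chart_row("CASE17"), "BIALLELIC_POSITIVE", kb,
                             has_cf_code = TRUE)
  expect_equal(lab17$label, "CF_CONFIRMED")
  expect_match(lab17$basis, "biallelic_genetics\\+clinical_features")
  # QNS sweat testing is treated as absent and falls through to features
  lab4 <- confirm_diagnosis(chart_row("CASE04"), "BIALLELIC_POSITIVE", kb,
                            has_cf_code = TRUE)
  expect_equal(lab4$label, "CF_CONFIRMED")
  # negative sweat workup in a heterozygote with CF codes: CRMS
  lab23 <- confirm_diagnosis(chart_row("CASE23"), "CARRIER", kb,
                             has_cf_code = TRUE)
  expect_equal(lab23$label, "CRMS")
  # bi-allelic genotype with an uninformative chart: insufficient, never CF
  lab24 <- confirm_diagnosis(chart_row("CASE24"), "BIALLELIC_POSITIVE", kb,
                             has_cf_code = FALSE)
  expect_equal(lab24$label, "INSUFFICIENT")
  # diagnostic sweat plus clinical presentation confirms even when the
  # second allele is missing from the knowledge base
  lab22 <- confirm_diagnosis(chart_row("CASE22"), "CARRIER", kb,
                             has_cf_code = TRUE)
  expect_equal(lab22$label, "CF_CONFIRMED")
  # code-positive individual with no variants and no evidence
  labx <- confirm_diagnosis(chart_row("EHR01"), "NEGATIVE", kb,
                            has_cf_code = TRUE)
  expect_equal(labx$label, "NOT_CF")
})

test_that("an intermediate sweat value does not block confirmation", {
  # sweat 50 is non-diagnostic; confirmation comes from genetics + features
  lab18 <- confirm_diagnosis(chart_row("CASE18"), "BIALLELIC_POSITIVE", kb,
                             has_cf_code = TRUE)
  expect_equal(lab18$label, "CF_CONFIRMED")
})

test_that("category assignment follows the screen-by-diagnosis mapping", {
  grid <- tidyr::expand_grid(
    status = c("BIALLELIC_POSITIVE", "CARRIER", "NEGATIVE"),
    label = c("CF_CONFIRMED", "CRMS", "INSUFFICIENT", "NOT_CF"))
  got <- assign_category(grid$status, grid$label)
  expected <- dplyr::case_when(
    grid$status == "BIALLELIC_POSITIVE" & grid$label == "CF_CONFIRMED" ~ "TP",
    grid$status == "BIALLELIC_POSITIVE" ~ "FP",
    grid$label == "CF_CONFIRMED" ~ "FN",
    TRUE ~ "TN")
  expect_equal(got$category, expected)
  expect_equal(got$potential_fp,
               grid$status == "BIALLELIC_POSITIVE" & grid$label == "INSUFFICIENT")
})

test_that("cohort adjudication reproduces the case-series confusion table", {
  cohort <- fixture_small(500)
  screen <- screen_cohort(cohort, kb)
  adj <- adjudicate_cohort(cohort, screen, kb = kb)
  ct <- adj$confusion
  expect_equal(c(ct$tp, ct$fp, ct$fn), c(21L, 3L, 1L))
  expect_equal(ct$tn, 500L - 25L)
  expect_equal(ct$n, 500L)
  # the three false positives are all flagged potential (insufficient data)
  fps <- dplyr::filter(adj$per_case, category == "FP")
  expect_equal(sort(fps$sample_id), c("CASE24", "CASE25", "CASE26"))
  expect_true(all(fps$potential_fp))
  # the false negative is the carrier whose second allele is unasserted
  expect_equal(adj$per_case$sample_id[adj$per_case$category == "FN"], "CASE22")
  # code-positive variant-free individuals adjudicate as true negatives
  ehr <- dplyr::filter(adj$per_case, grepl("^EHR", sample_id))
  expect_equal(nrow(ehr), 6L)
  expect_true(all(ehr$category == "TN"))
  # partition: every individual gets exactly one category
  expect_equal(nrow(adj$categories), 500L)
  expect_equal(anyDuplicated(adj$categories$sample_id), 0L)
})

test_that("a queued sample without a chart row is a hard error", {
  cohort <- fixture_small(100)
  cohort$chart <- dplyr::filter(cohort$chart, sample_id != "CASE05")
  screen <- screen_cohort(cohort, kb)
  expect_error(adjudicate_cohort(cohort, screen, kb = kb), "CASE05")
})

test_that("adding confirming facts moves categories only toward disease", {
  cohort <- fixture_small(100)
  screen <- screen_cohort(cohort, kb)
  base <- adjudicate_cohort(cohort, screen, kb = kb)
  # give the insufficient-data positive a diagnostic sweat test
  cohort2 <- cohort
  cohort2$chart$sweat_values[cohort2$chart$sample_id == "CASE24"] <- "95"
  adj2 <- adjudicate_cohort(cohort2, screen, kb = kb)
  expect_equal(adj2$confusion$tp, base$confusion$tp + 1L)
  expect_equal(adj2$confusion$fp, base$confusion$fp - 1L)
  cat24 <- dplyr::filter(adj2$per_case, sample_id == "CASE24")
  expect_equal(cat24$category, "TP")
  # enriching an already-confirmed case never demotes it
  cohort3 <- cohort
  cohort3$chart$bronchiectasis[cohort3$chart$sample_id == "CASE01"] <- "yes"
  adj3 <- adjudicate_cohort(cohort3, screen, kb = kb)
  expect_equal(adj3$confusion, base$confusion)
})

test_that("adjudication is independent of input row order", {
  cohort <- fixture_small(120)
  set.seed(5)
  shuffled <- cohort
  shuffled$chart <- shuffled$chart[sample(nrow(shuffled$chart)), ]
  shuffled$codes <- shuffled$codes[sample(nrow(shuffled$codes)), ]
  screen <- screen_cohort(cohort, kb)
  a <- adjudicate_cohort(cohort, screen, kb = kb)
  b <- adjudicate_cohort(shuffled, screen, kb = kb)
  expect_equal(a$confusion, b$confusion)
  expect_equal(a$categories, b$categories)
})

test_that("expert overrides replace rule labels and are audited", {
  cohort <- fixture_small(100)
  screen <- screen_cohort(cohort, kb)
  adj <- adjudicate_cohort(
    cohort, screen, kb = kb,
    overrides = tibble::tibble(sample_id = "CASE24", label = "CF_CONFIRMED"))
  row <- dplyr::filter(adj$per_case, sample_id == "CASE24")
  expect_equal(row$label, "CF_CONFIRMED")
  expect_equal(row$basis, "expert_override")
  expect_equal(row$category, "TP")
})
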