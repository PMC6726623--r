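kb <- kb_fixture()

test_that("the packaged knowledge base loads the expected assertions", {
  counts <- dplyr::count(kb$assertions, source)
  expect_equal(counts$n[counts$source == "CFTR2"], 12L)
  expect_equal(counts$n[counts$source == "ClinVar"], 13L)
  # the novel allele is absent from both sources
  expect_false("R1239S" %in% kb$assertions$legacy_name)
  # a known allele carries its tract modifier as annotation only
  r117h <- dplyr::filter(kb$assertions, legacy_name == "R117H")
  expect_true(all(r117h$tract_modifier == "T5/TG11"))
})

test_that("empty assertion tables load as an empty knowledge base", {
  empty <- tibble::tibble(legacy_name = character(), cdna_name = character(),
                          protein_name = character(), classification = character())
  kb0 <- load_kb(empty, empty, snapshot_date = "2018-09-15")
  expect_equal(nrow(kb0$assertions), 0L)
  expect_equal(classify_variant(kb0, "F508del"), "UNKNOWN")
})

test_that("duplicate and malformed rows are hard errors naming the culprit", {
  cftr2 <- readr::read_tsv(system.file("extdata", "kb_cftr2.tsv",
                                       package = "genoscreen"),
                           show_col_types = FALSE)
  dup <- dplyr::bind_rows(cftr2, dplyr::filter(cftr2, legacy_name == "F508del"))
  expect_error(load_kb(dup, cftr2[0, ], "2018-09-15"), "F508del")
  bad <- cftr2
  bad$cdna_name[3] <- "1521_1523delCTT"
  expect_error(load_kb(bad, cftr2[0, ], "2018-09-15"), "row 3")
})

test_that("unknown classification labels load but are flagged", {
  tab <- tibble::tibble(legacy_name = "X1", cdna_name = "c.1A>T",
                        protein_name = "", classification = "Probably causal")
  expect_warning(kb1 <- load_kb(tab, tab[0, ], "2018-09-15"), "Probably causal")
  expect_true(kb1$assertions$unknown_label)
  expect_equal(kb1$assertions$classification, "Probably causal")
})

test_that("the union pathogenicity rule reproduces the curated calls", {
  expect_equal(classify_variant(kb, "F508del"), "PATHOGENIC")
  # expert-curated 'varying consequence' qualifies through its ClinVar call
  expect_equal(classify_variant(kb, "R117H"), "PATHOGENIC")
  # a two-star pathogenic assertion is accepted (stars are not a filter)
  expect_equal(classify_variant(kb, "Q1476X"), "PATHOGENIC")
  expect_equal(classify_variant(kb, "S1235R"), "NOT_PATHOGENIC")
  expect_equal(classify_variant(kb, "R1239S"), "UNKNOWN")
})

test_that("era-restricted queries ignore later assertions", {
  expect_equal(classify_variant(kb, "Q1476X", as_of = "2009-01-01"), "UNKNOWN")
  expect_equal(classify_variant(kb, "Q1476X", as_of = "2013-06-01"), "PATHOGENIC")
  expect_error(classify_variant(kb, "F508del", as_of = "2020-01-01"),
               "snapshot")
})

test_that("classification is total and monotone in time over the fixture", {
  all_names <- unique(c(kb$assertions$legacy_name, "R1239S"))
  dates <- as.Date(c("2005-01-01", "2012-12-31", "2013-06-01", "2018-09-15"))
  calls_by_date <- lapply(dates, function(d) {
    classify_variants(kb, tibble::tibble(legacy_name = all_names), as_of = d)$call
  })
  for (calls in calls_by_date) {
    expect_true(all(calls %in% c("PATHOGENIC", "NOT_PATHOGENIC", "UNKNOWN")))
  }
  # once pathogenic, always pathogenic when assertions are only added
  for (i in seq_along(all_names)) {
    seq_calls <- vapply(calls_by_date, `[[`, "", i)
    first_path <- match("PATHOGENIC", seq_calls)
    if (!is.na(first_path)) {
      expect_true(all(seq_calls[first_path:length(seq_calls)] == "PATHOGENIC"),
                  info = all_names[i])
    }
  }
})

test_that("classification does not depend on input row order", {
  cftr2 <- readr::read_tsv(system.file("extdata", "kb_cftr2.tsv",
                                       package = "genoscreen"),
                           show_col_types = FALSE)
  clinvar <- readr::read_tsv(system.file("extdata", "kb_clinvar.tsv",
                                         package = "genoscreen"),
                             show_col_types = FALSE)
  ref_calls <- classify_variants(
    kb, tibble::tibble(legacy_name = sort(unique(cftr2$legacy_name))))$call
  set.seed(11)
  for (i in 1:5) {
    kb_shuffled <- load_kb(cftr2[sample(nrow(cftr2)), ],
                           clinvar[sample(nrow(clinvar)), ], "2018-09-15")
    calls <- classify_variants(
      kb_shuffled, tibble::tibble(legacy_name = sort(unique(cftr2$legacy_name))))$call
    expect_equal(calls, ref_calls)
  }
})

test_that("variant normalization trims to a minimal left-aligned form", {
  # shared suffix then shared prefix, keeping the anchor base
  v <- variant_tbl("7", 100, "TCGA", "TCA", legacy_name = "del1")
  expect_equal(v$pos, 101L)
  expect_equal(v$ref, "CG")
  expect_equal(v$alt, "C")
  # SNV inside a padded context
  v2 <- variant_tbl("7", 50, "AAGA", "AACA", legacy_name = "snv")
  expect_equal(c(v2$pos, v2$ref, v2$alt), c("52", "G", "C"))
  # identity key is stable under re-normalization
  expect_equal(normalize_variants(v)$variant_key, v$variant_key)
  expect_error(variant_tbl("7", 10, "A", "A"), "differ")
  expect_error(variant_tbl("7", 0, "A", "T"), "pos")
})

test_that("matching by normalized coordinates agrees with matching by name", {
  q <- tibble::tibble(chrom = "7", pos = 117101519L, ref = "AACTT", alt = "AA",
                      legacy_name = "")
  expect_equal(classify_variants(kb, q)$call, "PATHOGENIC")
})

test_that("transcript selection filters then maximizes coding length", {
  one <- tibble::tibble(transcript_id = "NM_000492.3", has_lrg = TRUE,
                        cds_length = 4443L, has_start_stop = TRUE)
  expect_equal(select_transcript(one), "NM_000492.3")
  two <- tibble::tibble(
    transcript_id = c("NM_A", "NM_B"), has_lrg = TRUE,
    cds_length = c(300L, 450L), has_start_stop = TRUE)
  expect_equal(select_transcript(two), "NM_B")
  none <- tibble::tibble(transcript_id = "NR_1", has_lrg = FALSE,
                         cds_length = 100L, has_start_stop = TRUE)
  expect_error(select_transcript(none), "no eligible transcript")
})

test_that("transcript ties break deterministically over all input orders", {
  cand <- tibble::tibble(
    transcript_id = c("NM_002", "NM_001", "NM_003"),
    has_lrg = c(TRUE, TRUE, TRUE),
    cds_length = c(300L, 300L, 200L),
    has_start_stop = c(TRUE, TRUE, TRUE))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    expect_equal(select_transcript(cand[p, ]), "NM_001")
  }
})
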