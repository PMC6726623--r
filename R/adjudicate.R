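#' Rule-based chart-review diagnosis
#'
#' Encodes the chart-review criteria as a deterministic rule engine. The
#' guiding principle is the clinical one: a CF diagnosis needs both
#' evidence of CFTR dysfunction and a clinical presentation of disease,
#' and no diagnosis is ever assumed from genotype alone.
#'
#' Definitions per reviewed individual:
#' * *diagnostic sweat*: any sweat chloride value `> 60` mmol/L (QNS
#'   results are treated as no usable value);
#' * *negative sweat workup*: at least one value recorded and all `< 60`;
#' * *bi-allelic genetics*: screen status `BIALLELIC_POSITIVE`, or a
#'   clinical genetic test reporting two knowledge-base pathogenic
#'   alleles (counting multiplicity, so a reported homozygote counts 2);
#' * *clinical features*: count of "yes" among bronchiectasis, pancreatic
#'   enzyme supplementation, longitudinal CF-clinic care, and a CF
#'   diagnosis documented in the EHR. Respiratory pseudomonas is recorded
#'   but not counted: colonization is common in non-CF bronchiectasis and
#'   counting it would confirm cases the expert reviewers did not.
#'
#' Rules, in order:
#' 1. diagnostic sweat + bi-allelic genetics -> `CF_CONFIRMED`;
#' 1b. diagnostic sweat + `>= 2` clinical features -> `CF_CONFIRMED`
#'    (dysfunction plus clinical presentation; covers a confirmed case
#'    whose second allele is absent from the knowledge base);
#' 2. no diagnostic sweat + bi-allelic genetics + `>= 2` clinical
#'    features -> `CF_CONFIRMED`;
#' 3. negative sweat workup + not bi-allelic + CF diagnosis context
#'    (codes or documented diagnosis) -> `CRMS`;
#' 4. bi-allelic genetics, nothing confirming, no negative sweat workup
#'    -> `INSUFFICIENT` (never CF by genotype alone);
#' 5. otherwise `NOT_CF`.
#'
#' @param chart Chart-fact tibble (see [read_chart()]), one row per
#'   individual to label.
#' @param screen_status Character vector aligned with `chart`:
#'   screen status of each individual.
#' @param kb A `variant_kb` used to classify clinically reported alleles.
#' @param has_cf_code Logical vector aligned with `chart`: diagnosis-code
#'   positivity (adds CF-diagnosis context for the CRMS rule).
#' @param as_of Classification date for clinical test alleles.
#' @return Tibble: `sample_id`, `label` (`CF_CONFIRMED`, `CRMS`,
#'   `INSUFFICIENT`, `NOT_CF`), `basis` (fired rule names, `+`-joined).
#' @export
confirm_diagnosis <- function(chart, screen_status, kb,
                              has_cf_code = rep(FALSE, nrow(chart)),
                              as_of = kb$snapshot_date) {
  chart <- as_tibble(chart)
  stopifnot(length(screen_status) == nrow(chart),
            length(has_cf_code) == nrow(chart))
  sweat <- parse_sweat_values(chart$sweat_values)
  sweat_high <- purrr::map_lgl(sweat, ~ length(.x) > 0 && any(.x > 60))
  sweat_low <- purrr::map_lgl(sweat, ~ length(.x) > 0 && all(.x < 60))
  n_path_clin <- purrr::map_int(chart$clinical_variants, function(s) {
    if (is.na(s) || s %in% c("", "-", "ND")) return(0L)
    names <- trimws(strsplit(s, ";")[[1]])
    names <- names[names != ""]
    if (length(names) == 0L) return(0L)
    calls <- classify_variants(kb, tibble(legacy_name = names), as_of = as_of)$call
    sum(calls == "PATHOGENIC")
  })
  biallelic <- screen_status == "BIALLELIC_POSITIVE" | n_path_clin >= 2L
  dx_doc <- chart$cf_dx_in_ehr == "yes" | has_cf_code
  features <- (chart$bronchiectasis == "yes") +
    (chart$pancreatic_supplement == "yes") +
    (chart$cf_clinic_care == "yes") +
    dx_doc
  label <- character(nrow(chart))
  basis <- character(nrow(chart))
  r1 <- sweat_high & biallelic
  r1b <- sweat_high & features >= 2L
  r2 <- !sweat_high & biallelic & features >= 2L
  confirmed <- r1 | r1b | r2
  crms <- !confirmed & sweat_low & !biallelic & dx_doc
  insufficient <- !confirmed & !crms & biallelic & !sweat_low
  label[confirmed] <- "CF_CONFIRMED"
  label[crms] <- "CRMS"
  label[insufficient] <- "INSUFFICIENT"
  label[label == ""] <- "NOT_CF"
  basis <- purrr::pmap_chr(list(r1, r1b, r2, crms, insufficient), function(a, b, c, d, e) {
    fired <- c("sweat_gt60+biallelic_genetics"[a],
               "sweat_gt60+clinical_features"[b],
               "biallelic_genetics+clinical_features"[c],
               "negative_sweat+monoallelic+cf_context"[d],
               "biallelic_without_confirmation"[e])
    if (length(fired) == 0L) "no_rule_fired" else paste(fired, collapse = "+")
  })
  tibble(sample_id = chart$sample_id, label = label, basis = basis)
}

#' Map screen status and diagnosis label to a diagnostic category
#'
#' `BIALLELIC_POSITIVE` with a confirmed diagnosis is a true positive;
#' with any other label a false positive (flagged *potential* when the
#' label is `INSUFFICIENT`: evidence was missing rather than negative).
#' A non-positive with a confirmed diagnosis is a false negative;
#' any other non-positive is a true negative.
#'
#' @param status Screen status vector.
#' @param label Diagnosis label vector.
#' @return Tibble: `category` (`TP`/`FP`/`TN`/`FN`), `potential_fp`
#'   (logical).
#' @export
assign_category <- function(status, label) {
  stopifnot(length(status) == length(label))
  positive <- status == "BIALLELIC_POSITIVE"
  confirmed <- label == "CF_CONFIRMED"
  tibble(
    category = case_when(
      positive & confirmed ~ "TP",
      positive & !confirmed ~ "FP",
      !positive & confirmed ~ "FN",
      TRUE ~ "TN"
    ),
    potential_fp = positive & label == "INSUFFICIENT"
  )
}

#' Adjudicate a screened cohort
#'
#' Runs the chart-review rule engine over the review queue and maps every
#' individual in the cohort to TP/FP/TN/FN. Individuals outside the queue
#' (screen negative and code negative) are true negatives by construction
#' and are never chart-reviewed. Every queued sample must have a chart
#' row; a missing row is a hard error.
#'
#' @param cohort A `gs_cohort`.
#' @param screen A `gs_screen` covering the cohort.
#' @param queue Review queue from [review_queue()] (rebuilt if `NULL`).
#' @param kb A `variant_kb`.
#' @param cs Code set used for queueing and CF-diagnosis context.
#' @param overrides Optional tibble `sample_id`, `label` of expert label
#'   overrides applied after the rule engine.
#' @return An object of class `gs_adjudication`: list with `categories`
#'   (tibble over all individuals: `sample_id`, `status`, `label`,
#'   `basis`, `category`, `potential_fp`, `reviewed`), `per_case` (the
#'   queued subset) and `confusion` (a [confusion_table()]).
#' @export
adjudicate_cohort <- function(cohort, screen, queue = NULL, kb,
                              cs = cf_code_set(), overrides = NULL) {
  if (is.null(queue)) queue <- review_queue(cohort, screen, cs)
  missing_chart <- setdiff(queue$sample_id, cohort$chart$sample_id)
  if (length(missing_chart) > 0L) {
    abort(paste0("queued sample has no chart row: ", missing_chart[[1L]]))
  }
  screen_tbl <- as_tibble(screen) |> select("sample_id", "status")
  cp <- code_positives(cohort, cs)
  chart_q <- cohort$chart |>
    semi_join(queue, by = "sample_id") |>
    inner_join(screen_tbl, by = "sample_id") |>
    inner_join(cp, by = "sample_id") |>
    arrange(.data$sample_id)
  labels <- confirm_diagnosis(select(chart_q, -"status", -"code_positive"),
                              chart_q$status, kb, chart_q$code_positive)
  if (!is.null(overrides)) {
    labels <- labels |>
      left_join(as_tibble(overrides) |> rename(override = "label"),
                by = "sample_id") |>
      mutate(label = dplyr::coalesce(.data$override, .data$label),
             basis = if_else(is.na(.data$override), .data$basis, "expert_override")) |>
      select(-"override")
  }
  per_case <- chart_q |>
    select("sample_id", "status") |>
    inner_join(labels, by = "sample_id") |>
    dplyr::bind_cols(assign_category(chart_q$status, labels$label)) |>
    mutate(reviewed = TRUE)
  rest <- screen_tbl |>
    anti_join(queue, by = "sample_id") |>
    mutate(label = NA_character_, basis = "not_reviewed", category = "TN",
           potential_fp = FALSE, reviewed = FALSE)
  categories <- bind_rows(per_case, rest) |> arrange(.data$sample_id)
  ct <- confusion_table(
    tp = sum(categories$category == "TP"),
    fp = sum(categories$category == "FP"),
    tn = sum(categories$category == "TN"),
    fn = sum(categories$category == "FN")
  )
  structure(list(categories = categories, per_case = per_case, confusion = ct),
            class = "gs_adjudication")
}

#' @export
print.gs_adjudication <- function(x, ...) {
  cat("<gs_adjudication>\n")
  print(x$confusion)
  invisible(x)
}

#' @rdname adjudicate_cohort
#' @param x A `gs_adjudication`.
#' @param ... Unused.
#' @method tidy gs_adjudication
#' @export
tidy.gs_adjudication <- function(x, ...) x$categories
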