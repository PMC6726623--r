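#' Define a diagnosis-code set
#'
#' @param name Short name for the code set.
#' @param codes Character vector of ICD-10 codes (normalized on input).
#' @return A `gs_code_set` (list with `name` and `codes`).
#' @export
code_set <- function(name, codes) {
  codes <- unique(normalize_icd10(codes))
  if (length(codes) == 0L) abort("a code set must contain at least one code")
  structure(list(name = name, codes = codes), class = "gs_code_set")
}

#' The cystic fibrosis ICD-10 code set
#'
#' E84.0 (CF with pulmonary manifestations), E84.11 (meconium ileus in
#' CF), E84.19 (CF with other intestinal manifestations), E84.8 (CF with
#' other manifestations), E84.9 (CF, unspecified).
#'
#' @return A `gs_code_set`.
#' @export
cf_code_set <- function() {
  code_set("cystic_fibrosis",
           c("E84.0", "E84.11", "E84.19", "E84.8", "E84.9"))
}

#' @export
print.gs_code_set <- function(x, ...) {
  cat("<gs_code_set>", x$name, ":", paste(x$codes, collapse = ", "), "\n")
  invisible(x)
}

#' Is an individual diagnosis-code positive?
#'
#' @param codes Character vector: one individual's ICD-10 code history
#'   (empty vector = no history).
#' @param cs A `gs_code_set`.
#' @return `TRUE` iff the history intersects the code set.
#' @examples
#' code_positive(c("E84.0", "J45.909"), cf_code_set())
#' @export
code_positive <- function(codes, cs) {
  stopifnot(inherits(cs, "gs_code_set"))
  length(intersect(normalize_icd10(codes), cs$codes)) > 0L
}

#' Per-sample code positivity over a cohort
#'
#' @param cohort A `gs_cohort`.
#' @param cs A `gs_code_set` (default [cf_code_set()]).
#' @return Tibble: `sample_id`, `code_positive` for every individual.
#' @export
code_positives <- function(cohort, cs = cf_code_set()) {
  hits <- cohort$codes |>
    filter(.data$icd10_code %in% cs$codes) |>
    distinct(.data$sample_id) |>
    mutate(code_positive = TRUE)
  cohort$samples |>
    select("sample_id") |>
    left_join(hits, by = "sample_id") |>
    mutate(code_positive = dplyr::coalesce(.data$code_positive, FALSE))
}

#' Assemble the open-chart-review queue
#'
#' The review queue is the union of all bi-allelic screen positives and
#' all diagnosis-code-positive individuals who are not screen positive.
#' Each entry carries exactly one reason; screen positivity wins the tie,
#' so nobody is queued twice. Ordering is deterministic (sorted by
#' `sample_id`).
#'
#' @param cohort A `gs_cohort`.
#' @param screen A `gs_screen` covering the cohort.
#' @param cs A `gs_code_set` (default [cf_code_set()]).
#' @return Tibble: `sample_id`, `queue_reason` (`"SCREEN_POSITIVE"` or
#'   `"CODE_POSITIVE_SCREEN_NEGATIVE"`).
#' @export
review_queue <- function(cohort, screen, cs = cf_code_set()) {
  missing <- setdiff(cohort$samples$sample_id, screen$sample_id)
  if (length(missing) > 0L) {
    abort(paste0("screen results do not cover the cohort; first missing: ",
                 missing[[1L]]))
  }
  cp <- code_positives(cohort, cs)
  screen |>
    as_tibble() |>
    select("sample_id", "status") |>
    inner_join(cp, by = "sample_id") |>
    mutate(queue_reason = case_when(
      .data$status == "BIALLELIC_POSITIVE" ~ "SCREEN_POSITIVE",
      .data$code_positive ~ "CODE_POSITIVE_SCREEN_NEGATIVE",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$queue_reason)) |>
    arrange(.data$sample_id) |>
    select("sample_id", "queue_reason")
}
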