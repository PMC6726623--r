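#' Run the full genome-first screening pipeline
#'
#' Orchestrates load -> screen -> code cross-reference -> chart
#' adjudication -> statistics -> concordance, with one log line per stage
#' (input/output counts) so the screening flow can be reconstructed from
#' the log alone. Outputs are sorted, so re-running on identical inputs
#' reproduces identical reports.
#'
#' @param cohort A `gs_cohort` (from [read_cohort()], [cohort_fixture()]
#'   or [simulate_cohort()]).
#' @param kb A `variant_kb`.
#' @param cs Diagnosis-code set (default [cf_code_set()]).
#' @param as_of Classification date (default: KB snapshot).
#' @param alpha,ci_method Passed to [compute_stats()].
#' @param out_dir Optional directory; when given, writes
#'   `flow_counts.json`, `per_case.tsv`, `screen_results.tsv`,
#'   `stats.tsv`, `stats.json` and `concordance.json`.
#' @param quiet Suppress stage logging.
#' @return A `gs_report`: list with `flow` (screen/queue/confusion
#'   counts), `screen`, `queue`, `adjudication`, `stats`, `concordance`.
#' @examples
#' \donttest{
#' report <- run_pipeline(cohort_fixture(n_total = 200), kb_fixture())
#' tidy(report$stats)
#' }
#' @export
run_pipeline <- function(cohort, kb, cs = cf_code_set(),
                         as_of = kb$snapshot_date, alpha = 0.05,
                         ci_method = "clopper-pearson", out_dir = NULL,
                         quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[genoscreen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  n <- cohort_size(cohort)
  log_stage("load: ", n, " individuals, ", nrow(cohort$calls), " stored calls")

  screen <- stage("screen", screen_cohort(cohort, kb, as_of = as_of))
  ssum <- screen_summary(screen)
  log_stage("screen: ", ssum$n_positive, " bi-allelic positive / ",
            ssum$n_carrier, " carrier / ", ssum$n_negative, " negative")

  queue <- stage("crossref", review_queue(cohort, screen, cs))
  log_stage("crossref: review queue of ", nrow(queue), " (",
            sum(queue$queue_reason == "SCREEN_POSITIVE"), " screen-positive + ",
            sum(queue$queue_reason == "CODE_POSITIVE_SCREEN_NEGATIVE"),
            " code-positive screen-negative)")

  adj <- stage("adjudicate", adjudicate_cohort(cohort, screen, queue, kb, cs))
  ct <- adj$confusion
  log_stage("adjudicate: TP ", ct$tp, ", FP ", ct$fp, ", TN ", ct$tn,
            ", FN ", ct$fn)

  stats <- stage("stats", compute_stats(ct, alpha = alpha, ci_method = ci_method))
  conc <- if (any(cohort$calls$platform == "CLINICAL_PANEL")) {
    stage("concordance",
          platform_concordance(cohort, kb, as_of = as_of, era_aware = TRUE))
  } else NULL
  if (!is.null(conc)) {
    log_stage("concordance: ", conc$n_concordant, "/", conc$n_comparable,
              " comparable samples concordant")
  }

  flow <- list(
    n_individuals = n,
    n_screen_positive = ssum$n_positive,
    n_carrier = ssum$n_carrier,
    n_screen_negative = ssum$n_negative,
    n_non_positive = n - ssum$n_positive,
    n_review_queue = nrow(queue),
    n_code_positive_screen_negative =
      sum(queue$queue_reason == "CODE_POSITIVE_SCREEN_NEGATIVE"),
    tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn
  )
  report <- structure(list(flow = flow, screen = screen, queue = queue,
                           adjudication = adj, stats = stats,
                           concordance = conc),
                      class = "gs_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle
#'
#' @param report A `gs_report`.
#' @param out_dir Output directory (created if needed). On any write
#'   error, partial outputs are removed.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("flow_counts.json", "per_case.tsv",
                                "screen_results.tsv", "stats.tsv",
                                "stats.json", "concordance.json"))
  names(paths) <- c("flow", "per_case", "screen", "stats_tsv", "stats_json",
                    "concordance")
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  jsonlite::write_json(report$flow, paths[["flow"]], auto_unbox = TRUE,
                       pretty = TRUE)
  readr::write_tsv(report$adjudication$per_case, paths[["per_case"]],
                   progress = FALSE)
  screen_out <- as_tibble(report$screen) |>
    filter(.data$status != "NEGATIVE") |>
    arrange(.data$sample_id)
  readr::write_tsv(screen_out, paths[["screen"]], progress = FALSE)
  readr::write_tsv(tidy(report$stats), paths[["stats_tsv"]], progress = FALSE)
  jsonlite::write_json(
    list(stats = tidy(report$stats), confusion = glance(report$stats)),
    paths[["stats_json"]], dataframe = "rows", pretty = TRUE, digits = NA)
  if (!is.null(report$concordance)) {
    conc <- report$concordance
    jsonlite::write_json(
      list(n_comparable = conc$n_comparable, n_concordant = conc$n_concordant,
           n_pairs = conc$n_pairs, discordances = conc$discordances,
           excluded_samples = conc$excluded_samples),
      paths[["concordance"]], dataframe = "rows", auto_unbox = TRUE,
      pretty = TRUE)
  } else {
    paths <- paths[names(paths) != "concordance"]
  }
  ok <- TRUE
  invisible(paths)
}

#' @export
print.gs_report <- function(x, ...) {
  cat("<gs_report>\n")
  cat("  cohort:", x$flow$n_individuals, "| screen positive:",
      x$flow$n_screen_positive, "| review queue:", x$flow$n_review_queue, "\n")
  print(x$stats)
  invisible(x)
}
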