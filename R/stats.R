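#' Confusion table
#'
#' @param tp,fp,tn,fn Non-negative counts; total must be positive.
#' @return A `gs_confusion` (one-row tibble).
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  if (sum(counts) == 0) abort("confusion table is empty")
  out <- tibble(tp = as.integer(tp), fp = as.integer(fp),
                tn = as.integer(tn), fn = as.integer(fn),
                n = as.integer(tp + fp + tn + fn))
  class(out) <- c("gs_confusion", class(out))
  out
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval via Beta quantiles:
#' `low = qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and
#' `high = qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#' Equivalent to inverting the binomial tail conditions
#' `P(X >= x) = alpha/2` and `P(X <= x) = alpha/2`.
#'
#' @param x Successes (`0 <= x <= n`).
#' @param n Trials (`>= 1`).
#' @param alpha Significance level (default 0.05 for a 95% interval).
#' @return Numeric `c(low, high)` as fractions.
#' @examples
#' round(100 * clopper_pearson_ci(21, 22), 2)  # 77.16 99.88
#' @export
clopper_pearson_ci <- function(x, n, alpha = 0.05) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    abort("x must be an integer in [0, n] with n >= 1")
  }
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Wilson score interval
#'
#' Offered as an alternative interval method; the default everywhere in
#' this package is the exact Clopper-Pearson interval.
#'
#' @inheritParams clopper_pearson_ci
#' @return Numeric `c(low, high)` as fractions.
#' @export
wilson_ci <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n) abort("x must be in [0, n] with n >= 1")
  z <- stats::qnorm(1 - alpha / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Screening performance statistics with exact confidence intervals
#'
#' From a confusion table computes sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, accuracy
#' `(tp+tn)/n` and prevalence `(tp+fn)/n`, each with a confidence
#' interval, on the percent scale. A statistic with a zero denominator is
#' reported as undefined (`NA`), never as 0.
#'
#' @param ct A `gs_confusion` from [confusion_table()].
#' @param alpha Significance level (default 0.05).
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return A `screening_stats` object; [tidy()] returns the per-statistic
#'   tibble (`statistic`, `estimate`, `conf.low`, `conf.high`, `x`, `n`),
#'   [glance()] a one-row summary, [autoplot()] a CI plot.
#' @examples
#' compute_stats(confusion_table(21, 3, 50753, 1))
#' @export
compute_stats <- function(ct, alpha = 0.05, ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(ct, "gs_confusion"))
  ci_method <- match.arg(ci_method)
  ci_fun <- switch(ci_method, "clopper-pearson" = clopper_pearson_ci,
                   "wilson" = wilson_ci)
  defs <- tibble(
    statistic = c("sensitivity", "specificity", "ppv", "npv",
                  "accuracy", "prevalence"),
    x = c(ct$tp, ct$tn, ct$tp, ct$tn, ct$tp + ct$tn, ct$tp + ct$fn),
    n = c(ct$tp + ct$fn, ct$tn + ct$fp, ct$tp + ct$fp, ct$tn + ct$fn,
          ct$n, ct$n)
  )
  rows <- purrr::pmap(defs, function(statistic, x, n) {
    if (n == 0) {
      tibble(statistic = statistic, estimate = NA_real_,
             conf.low = NA_real_, conf.high = NA_real_, x = x, n = n)
    } else {
      ci <- ci_fun(x, n, alpha)
      tibble(statistic = statistic, estimate = 100 * x / n,
             conf.low = 100 * ci[[1L]], conf.high = 100 * ci[[2L]], x = x, n = n)
    }
  })
  structure(list(stats = bind_rows(rows), confusion = ct,
                 alpha = alpha, ci_method = ci_method),
            class = "screening_stats")
}

#' @rdname compute_stats
#' @param x A `screening_stats`.
#' @param ... Unused.
#' @method tidy screening_stats
#' @export
tidy.screening_stats <- function(x, ...) x$stats

#' @rdname compute_stats
#' @method glance screening_stats
#' @export
glance.screening_stats <- function(x, ...) {
  dplyr::bind_cols(
    as_tibble(x$confusion),
    tibble(alpha = x$alpha, ci_method = x$ci_method)
  )
}

#' @export
print.screening_stats <- function(x, ...) {
  cat("<screening_stats> (", x$ci_method, ", ",
      100 * (1 - x$alpha), "% CI, percent scale)\n", sep = "")
  s <- x$stats
  for (i in seq_len(nrow(s))) {
    if (is.na(s$estimate[[i]])) {
      cat(sprintf("  %-11s undefined (zero denominator)\n", s$statistic[[i]]))
    } else {
      cat(sprintf("  %-11s %6.2f (%.2f-%.2f)  [%d/%d]\n", s$statistic[[i]],
                  s$estimate[[i]], s$conf.low[[i]], s$conf.high[[i]],
                  s$x[[i]], s$n[[i]]))
    }
  }
  invisible(x)
}

#' @rdname compute_stats
#' @param object A `screening_stats`.
#' @method autoplot screening_stats
#' @export
autoplot.screening_stats <- function(object, ...) {
  dat <- filter(object$stats, !is.na(.data$estimate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$statistic, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = "Screening performance",
                  subtitle = paste0(object$ci_method, " ",
                                    100 * (1 - object$alpha), "% intervals")) +
    ggplot2::theme_minimal()
}
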