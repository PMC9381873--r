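#' Impute shortage weeks with the series mean
#'
#' Stockout (shortage) weeks record a sentinel, not true demand. Replacing
#' them with the arithmetic mean of the observed weeks keeps the series
#' mean unchanged and shrinks the sample standard deviation by the factor
#' sqrt((n1 - 1)/(N - 1)), where n1 is the number of observed weeks and N
#' the total. Imputation is mandatory before outlier detection or fitting.
#'
#' @param series A [weekly_series()].
#' @return A list with `series` (the imputed series, missing mask cleared)
#'   and `report` (a `cleaning_report` data.frame with one row per imputed
#'   week: series_id, week, original, replaced_with, reason).
#' @examples
#' s <- weekly_series(c(2, 0, 4))
#' impute_missing(s)$series$values # 2 3 4
#' @export
impute_missing <- function(series) {
  stopifnot(inherits(series, "weekly_series"))
  obs <- !series$missing_mask
  if (!any(obs))
    stop("impute_missing: series '", series$series_id,
         "' has no observed weeks")
  if (!any(series$missing_mask)) {
    return(list(series = series, report = empty_cleaning_report()))
  }
  m <- mean(series$values[obs])
  out <- series
  idx <- which(series$missing_mask)
  report <- data.frame(series_id = series$series_id,
                       week = series$weeks[idx],
                       original = series$values[idx],
                       replaced_with = m,
                       reason = "imputed_missing",
                       stringsAsFactors = FALSE)
  out$values[idx] <- m
  out$missing_mask[] <- FALSE
  class(report) <- c("cleaning_report", "data.frame")
  list(series = out, report = report)
}

empty_cleaning_report <- function() {
  report <- data.frame(series_id = character(), week = integer(),
                       original = numeric(), replaced_with = numeric(),
                       reason = character(), stringsAsFactors = FALSE)
  class(report) <- c("cleaning_report", "data.frame")
  report
}

bind_cleaning_reports <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) return(empty_cleaning_report())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("cleaning_report", "data.frame")
  out
}

#' Grubbs test statistic
#'
#' Two-tailed Grubbs statistic G = max |Y_i - mean| / s, with s the sample
#' (N-1 divisor) standard deviation. The candidate outlier is the
#' observation attaining the maximum; ties go to the earliest week.
#'
#' @param values Numeric vector (or a [weekly_series()]) with at least 3
#'   observations and positive sample standard deviation.
#' @return A list with `G`, `candidate_week` (index into the series) and
#'   `candidate_value`.
#' @examples
#' grubbs_statistic(c(1, 2, 3, 100))$G # about 1.4998
#' @export
grubbs_statistic <- function(values) {
  weeks <- NULL
  if (inherits(values, "weekly_series")) {
    weeks <- values$weeks
    values <- values$values
  }
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("grubbs_statistic: need at least 3 observations")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("grubbs_statistic: zero sample standard deviation; ",
         "no outlier test possible")
  dev <- abs(values - mean(values))
  i <- which.max(dev)                  # which.max takes the earliest tie
  list(G = dev[i] / s,
       candidate_week = if (is.null(weeks)) i else weeks[i],
       candidate_value = values[i])
}

#' Grubbs critical value
#'
#' Critical value for the two-tailed single-outlier Grubbs test at
#' significance `alpha`:
#' G_crit = ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2)), where t is the
#' upper alpha/(2N) quantile of Student's t with N-2 degrees of freedom.
#' G_crit is always below the algebraic bound (N-1)/sqrt(N) on G.
#'
#' @param N Sample size, at least 3.
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return The critical value (dimensionless).
#' @examples
#' grubbs_critical(13) # 2.46203
#' @export
grubbs_critical <- function(N, alpha = 0.05) {
  if (N < 3L) stop("grubbs_critical: N must be at least 3")
  if (alpha <= 0 || alpha >= 1)
    stop("grubbs_critical: alpha must be in (0, 1)")
  tq <- stats::qt(1 - alpha / (2 * N), df = N - 2L)
  ((N - 1) / sqrt(N)) * sqrt(tq^2 / (N - 2L + tq^2))
}

#' Detect a single outlier with the Grubbs test
#'
#' Runs the two-tailed single-outlier Grubbs test on a fully observed
#' series: the candidate is flagged when G exceeds the critical value at
#' level `alpha`. Shortage weeks must be imputed first; running the test on
#' a series with missing weeks is an error, since sentinels would dominate
#' the statistic.
#'
#' @param series A [weekly_series()] with no missing weeks.
#' @param alpha Significance level. Default 0.05.
#' @return An object of class `outlier_report`: a list with `series_id`,
#'   `n`, `G`, `G_crit`, `candidate_week`, `candidate_value`, `is_outlier`,
#'   `replacement_value` (filled by [replace_outlier()]) and `alpha`.
#' @export
detect_outlier <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "weekly_series"))
  if (any(series$missing_mask))
    stop("detect_outlier: series '", series$series_id,
         "' has missing (shortage) weeks; imputation is mandatory before ",
         "outlier detection")
  g <- grubbs_statistic(series)
  gc <- grubbs_critical(length(series$values), alpha)
  structure(
    list(series_id = series$series_id, n = length(series$values),
         G = g$G, G_crit = gc, candidate_week = g$candidate_week,
         candidate_value = g$candidate_value, is_outlier = g$G > gc,
         replacement_value = NULL, alpha = alpha),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "Grubbs test for '%s' (N=%d, alpha=%.3g): G=%.4f, G_crit=%.4f -> %s\n",
    x$series_id, x$n, x$alpha, x$G, x$G_crit,
    if (x$is_outlier) paste0("outlier at week ", x$candidate_week,
                             " (value ", format(x$candidate_value), ")")
    else "no outlier"))
  if (!is.null(x$replacement_value))
    cat("  replaced with", format(x$replacement_value), "\n")
  invisible(x)
}

#' Winsorize a detected outlier to mean +/- 3 s
#'
#' Replaces the flagged observation with the series mean plus (for a high
#' outlier) or minus (for a low outlier) three sample standard deviations,
#' both computed excluding the flagged point, so that the replacement is
#' anchored to the healthy part of the distribution. The alternative policy
#' `"series_mean"` replaces the point with the plain mean of the remaining
#' observations.
#'
#' @param series The [weekly_series()] the report was computed on.
#' @param report An `outlier_report` with `is_outlier = TRUE`.
#' @param policy `"mean_plus_3s"` (default) or `"series_mean"`.
#' @return A list with the modified `series` and the updated `report`
#'   (with `replacement_value` recorded).
#' @export
replace_outlier <- function(series, report,
                            policy = c("mean_plus_3s", "series_mean")) {
  stopifnot(inherits(series, "weekly_series"),
            inherits(report, "outlier_report"))
  policy <- match.arg(policy)
  if (!isTRUE(report$is_outlier))
    stop("replace_outlier: report does not flag an outlier")
  idx <- match(report$candidate_week, series$weeks)
  rest <- series$values[-idx]
  m <- mean(rest)
  replacement <- if (policy == "series_mean") m else {
    s <- stats::sd(rest)
    if (series$values[idx] >= m) m + 3 * s else m - 3 * s
  }
  out <- series
  out$values[idx] <- replacement
  report$replacement_value <- replacement
  list(series = out, report = report)
}

#' Clean a series: impute shortages, then respond to an outlier
#'
#' Convenience pipeline used by the outlier-responsive planning approaches:
#' mean-imputes shortage weeks, runs the single-pass Grubbs test and, when
#' an outlier is flagged, winsorizes it. Ordering is enforced: imputation
#' always precedes the test.
#'
#' @param series A [weekly_series()].
#' @param alpha Grubbs significance level. Default 0.05.
#' @param policy Replacement policy, see [replace_outlier()].
#' @return A list with `series` (cleaned), `report` (a `cleaning_report`
#'   covering both imputations and any replacement) and `outlier` (the
#'   `outlier_report`, or `NULL` when the test was degenerate).
#' @export
clean_series <- function(series, alpha = 0.05,
                         policy = c("mean_plus_3s", "series_mean")) {
  policy <- match.arg(policy)
  imp <- impute_missing(series)
  s <- imp$series
  orep <- tryCatch(detect_outlier(s, alpha), error = function(e) NULL)
  rrep <- NULL
  if (!is.null(orep) && orep$is_outlier) {
    original <- orep$candidate_value
    rep2 <- replace_outlier(s, orep, policy)
    s <- rep2$series
    orep <- rep2$report
    rrep <- data.frame(series_id = s$series_id,
                       week = orep$candidate_week,
                       original = original,
                       replaced_with = orep$replacement_value,
                       reason = "outlier_3s", stringsAsFactors = FALSE)
  }
  list(series = s, report = bind_cleaning_reports(imp$report, rrep),
       outlier = orep)
}

#' Write a cleaning audit trail to CSV
#'
#' @param report A `cleaning_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
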