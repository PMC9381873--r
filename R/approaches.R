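#' Run a hierarchical planning approach over a pharmacy-chain panel
#'
#' The four planning approaches differ along two axes: the level at which
#' forecasting happens (chain aggregate vs per pharmacy) and whether the
#' data are cleaned of outliers first.
#'
#' \describe{
#'   \item{1}{forecast the aggregated chain series as-is (shortage
#'     sentinels flow into the sums).}
#'   \item{2}{aggregate, mean-impute chain-wide shortage weeks, run the
#'     Grubbs test and winsorize a detected outlier, then forecast the
#'     cleaned chain series.}
#'   \item{3}{mean-impute each pharmacy, forecast each pharmacy
#'     separately, and sum the per-pharmacy forecasts week-wise into the
#'     chain forecast.}
#'   \item{4}{as 3, but each pharmacy is additionally Grubbs-tested and
#'     winsorized before fitting.}
#' }
#'
#' Every requested method is fitted, accuracy (MAPE, MSE, U2 against the
#' summed/chain naive benchmark) is tabulated, and the method with the
#' lowest U2 is selected ([select_best()]). For approaches 3-4 the summed
#' forecasts are evaluated against the raw aggregated actuals by default,
#' so U2 measures real predictive quality; `evaluate_on_cleaned = TRUE`
#' evaluates against the sum of the cleaned series instead. Negative
#' combined forecasts (possible after severe shortages) are flagged in the
#' result, not rejected.
#'
#' @param panel A [chain_panel()].
#' @param approach Integer 1-4.
#' @param methods Subset of [forecast_methods()]. Default: all eight.
#' @param params Named list of per-method [smoothing_params()].
#' @param alpha Grubbs significance level for approaches 2 and 4.
#' @param policy Outlier replacement policy, see [replace_outlier()].
#' @param evaluate_on_cleaned For approaches 3-4: evaluate against cleaned
#'   aggregated actuals. Default `FALSE`.
#' @return An object of class `approach_result` with fields `approach`,
#'   `accuracy` (per-method `accuracy_report`), `best_method`, `cleaning`
#'   (audit trail), `forecasts` (named list of fitted/combined traces),
#'   `chain_forecast` (the best method's trace), `actuals` (the evaluation
#'   series) and `negative_forecast_weeks`.
#' @examples
#' p <- generate_chain(default_chain_specs(shortage = FALSE), seed = 1)
#' res <- run_approach(p, 1, methods = c("naive", "ses", "moving_average"))
#' res$best_method
#' @export
run_approach <- function(panel, approach = 1L,
                         methods = forecast_methods(),
                         params = default_method_params(),
                         alpha = 0.05,
                         policy = c("mean_plus_3s", "series_mean"),
                         evaluate_on_cleaned = FALSE) {
  stopifnot(inherits(panel, "chain_panel"))
  approach <- as.integer(approach)
  if (!approach %in% 1:4) stop("run_approach: approach must be 1, 2, 3 or 4")
  methods <- match.arg(methods, forecast_methods(), several.ok = TRUE)
  methods <- forecast_methods()[forecast_methods() %in% methods]
  policy <- match.arg(policy)
  if (!"naive" %in% methods)
    stop("run_approach: the naive benchmark must be among the methods")

  cleaning <- empty_cleaning_report()
  if (approach %in% c(1L, 2L)) {
    if (approach == 1L) {
      chain <- aggregate_chain(panel, keep_sentinels = TRUE)
    } else {
      cl <- clean_series(aggregate_chain(panel), alpha, policy)
      chain <- cl$series
      cleaning <- cl$report
    }
    actuals <- chain$values
    fits <- lapply(methods, function(m)
      tryCatch(pharma_forecast(chain, m, params = params[[m]]),
               error = function(e) conditionMessage(e)))
    names(fits) <- methods
  } else {
    cleaned <- lapply(panel$pharmacies, function(s) {
      if (approach == 3L) {
        imp <- impute_missing(s)
        list(series = imp$series, report = imp$report)
      } else {
        cl <- clean_series(s, alpha, policy)
        list(series = cl$series, report = cl$report)
      }
    })
    cleaning <- do.call(bind_cleaning_reports,
                        lapply(cleaned, function(x) x$report))
    actuals <- if (evaluate_on_cleaned)
      rowSums(vapply(cleaned, function(x) x$series$values,
                     numeric(length(panel$weeks))))
    else aggregate_chain(panel, keep_sentinels = TRUE)$values
    fits <- lapply(methods, function(m) {
      tryCatch({
        members <- lapply(cleaned, function(x)
          pharma_forecast(x$series, m, params = params[[m]]))
        combine_forecasts(members, actuals, panel$weeks, m, params[[m]])
      }, error = function(e) conditionMessage(e))
    })
    names(fits) <- methods
  }

  # a method whose recursion is undefined on these data (e.g. the
  # multiplicative form on zero-sentinel sums) is reported, not fatal
  skipped <- vapply(fits, is.character, logical(1))
  skipped_msgs <- unlist(fits[skipped])
  fits <- fits[!skipped]
  if (is.null(fits[["naive"]]))
    stop("run_approach: the naive benchmark could not be fitted: ",
         skipped_msgs[["naive"]])

  naive_fit <- fits[["naive"]]
  accuracy <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(evaluate_forecast(f, naive_fit, actuals = actuals,
                                    allow_sentinel = TRUE))))
  rownames(accuracy) <- NULL
  class(accuracy) <- c("accuracy_report", "data.frame")
  best <- select_best(accuracy)
  neg <- lapply(fits, function(f) {
    wk <- panel$weeks[!is.na(f$fitted) & f$fitted < 0]
    if (length(wk)) wk else integer(0)
  })
  structure(
    list(approach = approach, accuracy = accuracy, best_method = best,
         cleaning = cleaning, forecasts = fits,
         chain_forecast = fits[[best]], actuals = actuals,
         negative_forecast_weeks = neg[vapply(neg, length, 1L) > 0],
         skipped = skipped_msgs),
    class = "approach_result")
}

# sum per-pharmacy fits into one chain-level trace; warm-up weeks are the
# union of the members' warm-ups (rowSums propagates NA)
combine_forecasts <- function(members, actuals, weeks, method, params) {
  t_n <- length(weeks)
  fitted_mat <- vapply(members, function(f) f$fitted, numeric(t_n))
  fitted <- rowSums(fitted_mat)
  future <- Reduce(`+`, lapply(members, function(f) f$future))
  structure(
    list(method = method,
         series = weekly_series(pmax(actuals, 0), series_id = "chain",
                                weeks = weeks,
                                missing = rep(FALSE, t_n)),
         fitted = fitted, future = future,
         components = list(level = sum(vapply(
           members, function(f) f$components$level, numeric(1)))),
         params = params,
         state = list(kind = "combined", members = members)),
    class = "pharma_forecast")
}

#' @export
print.approach_result <- function(x, ...) {
  cat("Planning approach", x$approach, "\n")
  print(x$accuracy)
  cat("Selected method (lowest U2):", x$best_method, "\n")
  if (nrow(x$cleaning))
    cat("Cleaning actions:", nrow(x$cleaning), "(",
        paste(unique(x$cleaning$reason), collapse = ", "), ")\n")
  if (length(x$negative_forecast_weeks))
    cat("Warning: negative fitted forecasts for ",
        paste(names(x$negative_forecast_weeks), collapse = ", "), "\n")
  if (length(x$skipped))
    cat("Skipped (recursion undefined on these data):",
        paste(names(x$skipped), collapse = ", "), "\n")
  cat("Next-week chain forecast:", format(x$chain_forecast$future[1L]), "\n")
  invisible(x)
}

#' Select the most accurate method by the U2 criterion
#'
#' Returns the method with the smallest U2 ratio; ties are broken by
#' registry order ([forecast_methods()]). When no method beats the naive
#' benchmark (all U2 >= 1), the naive method is returned.
#'
#' @param reports An `accuracy_report` data.frame (columns `method`, `u2`).
#' @return The selected method name.
#' @export
select_best <- function(reports) {
  reports <- as.data.frame(reports)
  if (!nrow(reports)) stop("select_best: no accuracy reports")
  ord <- order(match(reports$method, forecast_methods()))
  reports <- reports[ord, , drop = FALSE]
  if (min(reports$u2) >= 1 && "naive" %in% reports$method) return("naive")
  reports$method[which.min(reports$u2)]
}

#' Safety-stock uplift for growing drug categories
#'
#' When a drug category is known to grow year over year (e.g. alimentary
#' 6%, respiratory 4%, cardiovascular 1%, dermatological 10%), a purely
#' historical forecast should be raised by that growth rate as safety
#' stock.
#'
#' @param forecast Forecast quantity (units).
#' @param growth_rate Annual growth rate as a fraction, non-negative.
#' @return `forecast * (1 + growth_rate)`.
#' @examples
#' safety_stock_uplift(100, 0.06) # 106
#' @export
safety_stock_uplift <- function(forecast, growth_rate) {
  if (any(growth_rate < 0))
    stop("safety_stock_uplift: growth_rate must be non-negative")
  forecast * (1 + growth_rate)
}
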