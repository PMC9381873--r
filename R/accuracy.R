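#' Mean absolute percentage error
#'
#' MAPE over the weeks where a fitted one-step forecast is defined (warm-up
#' weeks are excluded; different methods therefore evaluate over different
#' denominators, e.g. 12 weeks for naive/SES but 11 for a window-2 moving
#' average on a 13-week series). Each week's error is scaled by that week's
#' actual.
#'
#' Actuals of exactly zero are always an error (division by zero). Actuals
#' at or below `sentinel_epsilon` -- shortage sentinels such as 0.0001 --
#' are refused by default because they blow the percentage up by orders of
#' magnitude; set `allow_sentinel = TRUE` to divide through regardless
#' (reproducing the exploding MAPE seen when sentinel-laden chain series
#' are evaluated uncleaned).
#'
#' @param actuals Numeric vector of actual values.
#' @param fitted Numeric vector of one-step forecasts, `NA` on warm-up
#'   weeks.
#' @param allow_sentinel Permit sentinel-valued actuals. Default `FALSE`.
#' @param sentinel_epsilon Sentinel threshold. Default 0.001.
#' @return MAPE in percent.
#' @examples
#' mape(c(10, 20), c(NA, 10)) # 50
#' @export
mape <- function(actuals, fitted, allow_sentinel = FALSE,
                 sentinel_epsilon = 0.001) {
  ev <- eval_weeks(actuals, fitted)
  a <- actuals[ev]; f <- fitted[ev]
  if (!allow_sentinel) {
    if (any(a == 0))
      stop("mape: evaluated actual of 0 (division by zero); impute ",
           "shortage weeks first")
    if (any(a <= sentinel_epsilon))
      stop("mape: evaluated actuals contain shortage sentinels; impute ",
           "first or set allow_sentinel = TRUE")
  }
  mean(abs(a - f) / a) * 100
}

#' Mean squared error
#'
#' MSE over the weeks where a fitted one-step forecast is defined; warm-up
#' weeks are excluded, so the evaluation window follows the method.
#'
#' @inheritParams mape
#' @return Mean squared error (squared sales units).
#' @export
mse <- function(actuals, fitted) {
  ev <- eval_weeks(actuals, fitted)
  mean((actuals[ev] - fitted[ev])^2)
}

eval_weeks <- function(actuals, fitted) {
  if (length(actuals) != length(fitted))
    stop("actuals and fitted forecasts have different lengths")
  ev <- !is.na(fitted)
  if (!any(ev)) stop("no evaluated weeks: all fitted values are undefined")
  ev
}

#' Theil-type U2 ratio against the naive benchmark
#'
#' The ratio MSE(method) / MSE(naive). Note this is the plain MSE ratio
#' (no square root), diverging from the textbook Theil U2: values below 1
#' mean the method beats the naive benchmark, 1 is the naive method against
#' itself.
#'
#' @param mse_method MSE of the method under evaluation.
#' @param mse_naive MSE of the naive forecast on the same series; must be
#'   positive.
#' @return The dimensionless ratio.
#' @examples
#' theil_u2(6852580, 11814118) # 0.58003
#' @export
theil_u2 <- function(mse_method, mse_naive) {
  if (mse_naive <= 0)
    stop("theil_u2: naive MSE must be positive")
  mse_method / mse_naive
}

#' Accuracy report for one fitted forecaster
#'
#' Bundles MAPE, MSE and the U2 ratio for a fitted model against the
#' series it was fitted on. Each method's MAPE/MSE use that method's own
#' evaluated weeks; the naive MSE in the U2 denominator uses the naive
#' method's evaluated weeks. By default the evaluation windows are NOT
#' forced to a common set (this mirrors how the methods are compared in
#' practice on short panels); `common_window = TRUE` restricts every
#' method to the intersection of evaluated weeks, the statistically
#' cleaner alternative.
#'
#' @param fit A [pharma_forecast()] object.
#' @param naive_fit The naive `pharma_forecast` on the same series; fitted
#'   internally when `NULL`.
#' @param actuals Optional numeric vector to evaluate against (defaults to
#'   the series the model was fitted on; the outlier-responsive approaches
#'   pass the original uncleaned actuals here).
#' @param allow_sentinel Passed to [mape()].
#' @param common_window Force a common evaluation window. Default `FALSE`.
#' @return An object of class `accuracy_report`: a one-row data.frame with
#'   columns `method`, `mape`, `mse`, `u2`, `n_forecasts`.
#' @export
evaluate_forecast <- function(fit, naive_fit = NULL, actuals = NULL,
                              allow_sentinel = FALSE,
                              common_window = FALSE) {
  stopifnot(inherits(fit, "pharma_forecast"))
  if (is.null(actuals)) actuals <- fit$series$values
  if (is.null(naive_fit))
    naive_fit <- pharma_forecast(fit$series, "naive",
                                 params = smoothing_params(
                                   horizon = fit$params$horizon))
  stopifnot(inherits(naive_fit, "pharma_forecast"))
  if (length(naive_fit$fitted) != length(fit$fitted))
    stop("evaluate_forecast: fits cover series of different lengths")
  f <- fit$fitted
  fn <- naive_fit$fitted
  if (common_window) {
    keep <- !is.na(f) & !is.na(fn)
    f[!keep] <- NA_real_
    fn[!keep] <- NA_real_
  }
  m_mse <- mse(actuals, f)
  n_mse <- mse(actuals, fn)
  out <- data.frame(
    method = fit$method,
    mape = mape(actuals, f, allow_sentinel = allow_sentinel),
    mse = m_mse,
    u2 = theil_u2(m_mse, n_mse),
    n_forecasts = sum(!is.na(f)),
    stringsAsFactors = FALSE)
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Accuracy table for several methods on one series
#'
#' Fits every requested method to the series and tabulates MAPE, MSE and
#' U2, one row per method in registry order.
#'
#' @param series A [weekly_series()] (or numeric vector) with no missing
#'   weeks.
#' @param methods Methods to fit. Default: all eight.
#' @param params Named list of [smoothing_params()] per method. Default:
#'   [default_method_params()].
#' @param ... Passed to [evaluate_forecast()].
#' @return An `accuracy_report` data.frame with one row per method.
#' @examples
#' y <- weekly_series(c(12, 15, 13, 16, 14, 18, 15, 17))
#' accuracy_table(y, methods = c("naive", "ses", "moving_average"))
#' @export
accuracy_table <- function(series, methods = forecast_methods(),
                           params = default_method_params(), ...) {
  series <- as_weekly_series(series)
  methods <- match.arg(methods, forecast_methods(), several.ok = TRUE)
  naive_fit <- pharma_forecast(series, "naive")
  rows <- lapply(methods, function(m) {
    fit <- pharma_forecast(series, m, params = params[[m]])
    evaluate_forecast(fit, naive_fit, ...)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, digits_mape = 2L, digits_u2 = 5L, ...) {
  # display rounding only; stored values keep full precision
  shown <- data.frame(method = x$method,
                      MAPE = round(x$mape, digits_mape),
                      MSE = round(x$mse),
                      U2 = round(x$u2, digits_u2),
                      n = x$n_forecasts)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
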