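#' Smoothing parameters
#'
#' Container for the tunable constants of the exponential-smoothing family:
#' `alpha` (level weight), `beta` (trend weight), `gamma` (seasonal weight),
#' all in [0, 1]; `window`, the moving-average interval; `period`, the
#' seasonal period P; and `horizon`, the forecast lead. Weekly retail data
#' over a quarter carries no modelled seasonality, so `period` defaults to 1.
#'
#' @param alpha Level smoothing weight in [0, 1].
#' @param beta Trend smoothing weight in [0, 1].
#' @param gamma Seasonal (or second-pass) smoothing weight in [0, 1].
#' @param window Moving-average interval, positive integer.
#' @param period Seasonal period P, positive integer.
#' @param horizon Forecast lead (number of future weeks), positive integer.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(alpha = 0.2, beta = 0.15, gamma = 0.05,
                             window = 2L, period = 1L, horizon = 1L) {
  for (nm in c("alpha", "beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("smoothing_params: '", nm, "' must be a single value in [0, 1]")
  }
  for (nm in c("window", "period", "horizon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop("smoothing_params: '", nm, "' must be a positive integer")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 window = as.integer(window), period = as.integer(period),
                 horizon = as.integer(horizon)),
            class = "smoothing_params")
}

#' @export
print.smoothing_params <- function(x, ...) {
  cat(sprintf(
    "smoothing_params: alpha=%.3g beta=%.3g gamma=%.3g window=%d period=%d horizon=%d\n",
    x$alpha, x$beta, x$gamma, x$window, x$period, x$horizon))
  invisible(x)
}

#' The forecasting-method registry
#'
#' Canonical names of the eight supported methods, in registry order. The
#' order matters: accuracy-based selection breaks ties by the first match
#' in this order.
#'
#' @return Character vector of the eight method names.
#' @export
forecast_methods <- function() {
  c("naive", "moving_average", "ses", "double_exp", "holt_linear",
    "hw_no_trend", "hw_additive", "hw_multiplicative")
}

#' Default smoothing parameters per method
#'
#' The fixed operating constants used throughout the package: single
#' exponential smoothing alpha = 0.2; moving average window 2; Holt's
#' linear alpha = 0.4, beta = 0.7; Holt-Winters no-trend alpha = 0.2,
#' gamma = 0.05; Holt-Winters additive and multiplicative alpha = 0.2,
#' beta = 0.15, gamma = 0.05; double smoothing alpha = 0.2, gamma = 0.15.
#' Parameters are fixed inputs, not optimized.
#'
#' @param method Optional single method name; if given, return that
#'   method's `smoothing_params`, otherwise the full named list.
#' @param horizon Forecast lead applied to every method. Default 1.
#' @return A `smoothing_params` object, or a named list of them.
#' @export
default_method_params <- function(method = NULL, horizon = 1L) {
  all <- list(
    naive             = smoothing_params(horizon = horizon),
    moving_average    = smoothing_params(window = 2L, horizon = horizon),
    ses               = smoothing_params(alpha = 0.2, horizon = horizon),
    double_exp        = smoothing_params(alpha = 0.2, gamma = 0.15,
                                         horizon = horizon),
    holt_linear       = smoothing_params(alpha = 0.4, beta = 0.7,
                                         horizon = horizon),
    hw_no_trend       = smoothing_params(alpha = 0.2, gamma = 0.05,
                                         horizon = horizon),
    hw_additive       = smoothing_params(alpha = 0.2, beta = 0.15,
                                         gamma = 0.05, horizon = horizon),
    hw_multiplicative = smoothing_params(alpha = 0.2, beta = 0.15,
                                         gamma = 0.05, horizon = horizon))
  if (is.null(method)) return(all)
  method <- match.arg(method, forecast_methods())
  all[[method]]
}
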