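#' Fit a weekly sales forecaster
#'
#' The central fitting function of the package. Applies one of eight
#' smoothing-family methods to a weekly sales series and returns the
#' one-step-ahead fitted forecasts, the future-horizon forecasts and the
#' final state (level, trend, seasonal factors) as a classed model object.
#'
#' Methods (registry order, see [forecast_methods()]):
#' \describe{
#'   \item{naive}{every forecast is the last observation.}
#'   \item{moving_average}{forecast is the mean of the last `window`
#'     observations; weeks 1..window are warm-up.}
#'   \item{ses}{single exponential smoothing,
#'     F(t+1) = alpha*Y(t) + (1-alpha)*F(t), initialized F(2) = Y(1).}
#'   \item{double_exp}{Brown-style double smoothing with two weights:
#'     S1(t) = alpha*Y(t) + (1-alpha)*S1(t-1),
#'     S2(t) = gamma*S1(t) + (1-gamma)*S2(t-1); level = 2*S1 - S2,
#'     trend = (alpha/(1-alpha))*(S1 - S2).}
#'   \item{holt_linear}{Holt's linear trend:
#'     a(t) = alpha*Y(t) + (1-alpha)*(a(t-1)+b(t-1)),
#'     b(t) = beta*(a(t)-a(t-1)) + (1-beta)*b(t-1);
#'     forecast a(t) + k*b(t).}
#'   \item{hw_no_trend}{Holt-Winters with additive seasonality and no
#'     trend term.}
#'   \item{hw_additive}{Holt-Winters additive seasonality, linear trend.}
#'   \item{hw_multiplicative}{Holt-Winters multiplicative seasonality,
#'     linear trend; requires strictly positive data.}
#' }
#'
#' One-step fitted forecasts are aligned so that `fitted[t]` is the forecast
#' of week t made from the state after week t-1; warm-up weeks (week 1 for
#' all recursive methods, weeks 1..window for the moving average) are `NA`.
#'
#' Initialization of the Holt family is a modelling choice, controlled by
#' `init`: `"ols_on_first_m"` (default for the trend methods) takes the
#' ordinary-least-squares line through the first `init_m` observations for
#' the starting level and trend; `"first_observation"` starts at Y(1) with
#' zero trend; `"explicit"` uses `init_values`. Seasonal factors start at 0
#' (additive forms) or 1 (multiplicative) unless supplied. The series must
#' be free of shortage weeks: impute first (see [impute_missing()]).
#'
#' @param series A [weekly_series()] or a plain numeric vector.
#' @param method One of [forecast_methods()].
#' @param params A [smoothing_params()]; defaults to
#'   [default_method_params()] for the chosen method.
#' @param init Initialization rule for level/trend methods; see Details.
#' @param init_values For `init = "explicit"`: a list with optional
#'   components `level` (a single number), `trend` (a single number) and
#'   `seasonal` (length-`period` vector, ordered oldest to newest, covering
#'   the weeks just before the recursion starts).
#' @param init_m Number of leading observations used by
#'   `"ols_on_first_m"`. Default 2.
#' @return An object of class `pharma_forecast` with fields `method`,
#'   `series`, `fitted`, `future`, `components`, `params` and `state`.
#' @examples
#' y <- weekly_series(c(12, 15, 13, 16, 14, 18))
#' f <- pharma_forecast(y, "ses")
#' fitted(f)
#' predict(f, horizon = 3)
#' @export
pharma_forecast <- function(series, method = forecast_methods(),
                            params = NULL,
                            init = c("default", "ols_on_first_m",
                                     "first_observation", "explicit"),
                            init_values = NULL, init_m = 2L) {
  series <- as_weekly_series(series)
  method <- match.arg(method)
  init <- match.arg(init)
  if (is.null(params)) params <- default_method_params(method)
  stopifnot(inherits(params, "smoothing_params"))
  if (any(series$missing_mask))
    stop("pharma_forecast: series '", series$series_id,
         "' has shortage (missing) weeks ",
         paste(series$weeks[series$missing_mask], collapse = ", "),
         "; impute them first, e.g. with impute_missing()")
  y <- series$values
  t_n <- length(y)
  h <- params$horizon
  eng <- switch(method,
    naive             = engine_naive(y, h),
    moving_average    = engine_moving_average(y, params$window, h),
    ses               = engine_ses(y, params$alpha, h),
    double_exp        = engine_double_exp(y, params$alpha, params$gamma, h,
                                          init, init_values),
    holt_linear       = engine_holt(y, params$alpha, params$beta, h,
                                    init, init_values, init_m),
    hw_no_trend       = engine_hw(y, params$alpha, 0, params$gamma,
                                  params$period, h, init, init_values,
                                  init_m, trend = FALSE,
                                  seasonal = "additive"),
    hw_additive       = engine_hw(y, params$alpha, params$beta, params$gamma,
                                  params$period, h, init, init_values,
                                  init_m, trend = TRUE,
                                  seasonal = "additive"),
    hw_multiplicative = engine_hw(y, params$alpha, params$beta, params$gamma,
                                  params$period, h, init, init_values,
                                  init_m, trend = TRUE,
                                  seasonal = "multiplicative"))
  structure(
    list(method = method, series = series, fitted = eng$fitted,
         future = eng$future, components = eng$components,
         params = params, state = eng$state),
    class = "pharma_forecast")
}

# ---- engines ---------------------------------------------------------------

engine_naive <- function(y, h) {
  t_n <- length(y)
  if (t_n < 2L) stop("naive method needs at least 2 weeks")
  fitted <- c(NA_real_, y[-t_n])
  list(fitted = fitted, future = rep(y[t_n], h),
       components = list(level = y[t_n]),
       state = list(kind = "level", level = y[t_n]))
}

engine_moving_average <- function(y, window, h) {
  t_n <- length(y)
  if (window >= t_n)
    stop("moving average window (", window,
         ") must be smaller than the series length (", t_n, ")")
  fitted <- rep(NA_real_, t_n)
  for (t in (window + 1L):t_n) fitted[t] <- mean(y[(t - window):(t - 1L)])
  lastavg <- mean(y[(t_n - window + 1L):t_n])
  list(fitted = fitted, future = rep(lastavg, h),
       components = list(level = lastavg),
       state = list(kind = "level", level = lastavg))
}

engine_ses <- function(y, alpha, h) {
  t_n <- length(y)
  if (t_n < 2L) stop("single exponential smoothing needs at least 2 weeks")
  f <- rep(NA_real_, t_n + 1L)
  f[2L] <- y[1L]                       # F2 = Y1
  for (t in 2L:t_n) f[t + 1L] <- alpha * y[t] + (1 - alpha) * f[t]
  list(fitted = f[seq_len(t_n)], future = rep(f[t_n + 1L], h),
       components = list(level = f[t_n + 1L]),
       state = list(kind = "level", level = f[t_n + 1L]))
}

# starting level/trend from the chosen initialization rule
init_level_trend <- function(y, init, init_values, init_m,
                             default = "ols_on_first_m") {
  if (init == "default") init <- default
  switch(init,
    first_observation = list(level = y[1L], trend = 0),
    ols_on_first_m = {
      m <- max(2L, as.integer(init_m))
      if (m > length(y)) stop("init_m exceeds the series length")
      tt <- seq_len(m)
      b <- stats::cov(tt, y[tt]) / stats::var(tt)
      a <- mean(y[tt]) - b * mean(tt) + b * 1  # level at week 1
      list(level = a, trend = b)
    },
    explicit = {
      if (is.null(init_values))
        stop("init = 'explicit' requires init_values")
      list(level = if (!is.null(init_values$level)) init_values$level
                   else y[1L],
           trend = if (!is.null(init_values$trend)) init_values$trend else 0)
    })
}

engine_holt <- function(y, alpha, beta, h, init, init_values, init_m) {
  t_n <- length(y)
  if (t_n < 3L) stop("Holt's linear method needs at least 3 weeks")
  st <- init_level_trend(y, init, init_values, init_m)
  a <- st$level; b <- st$trend
  fitted <- rep(NA_real_, t_n)
  for (t in 2L:t_n) {
    fitted[t] <- a + b
    a_prev <- a
    a <- alpha * y[t] + (1 - alpha) * (a_prev + b)
    b <- beta * (a - a_prev) + (1 - beta) * b
  }
  list(fitted = fitted, future = a + seq_len(h) * b,
       components = list(level = a, trend = b),
       state = list(kind = "linear", level = a, trend = b))
}

engine_double_exp <- function(y, alpha, gamma, h, init, init_values) {
  t_n <- length(y)
  if (t_n < 2L) stop("double exponential smoothing needs at least 2 weeks")
  if (alpha >= 1)
    stop("double exponential smoothing requires alpha < 1 ",
         "(trend factor alpha/(1-alpha) is degenerate at alpha = 1)")
  s1 <- s2 <- if (init == "explicit" && !is.null(init_values$level))
    init_values$level else y[1L]
  fitted <- rep(NA_real_, t_n)
  level <- 2 * s1 - s2
  trend <- (alpha / (1 - alpha)) * (s1 - s2)
  for (t in 2L:t_n) {
    fitted[t] <- level + trend
    s1 <- alpha * y[t] + (1 - alpha) * s1
    s2 <- gamma * s1 + (1 - gamma) * s2
    level <- 2 * s1 - s2
    trend <- (alpha / (1 - alpha)) * (s1 - s2)
  }
  list(fitted = fitted, future = level + seq_len(h) * trend,
       components = list(level = level, trend = trend, s1 = s1, s2 = s2),
       state = list(kind = "linear", level = level, trend = trend))
}

# Holt-Winters family. Seasonal factors are stored for weeks (2-P)..T; the
# initial P entries cover the weeks just before the recursion starts
# (oldest first). trend=FALSE freezes b at 0 (the no-trend variant).
engine_hw <- function(y, alpha, beta, gamma, period, h, init, init_values,
                      init_m, trend, seasonal) {
  t_n <- length(y)
  P <- period
  if (t_n < P + 1L)
    stop("Holt-Winters needs at least period + 1 = ", P + 1L, " weeks")
  if (seasonal == "multiplicative" && any(y <= 0))
    stop("multiplicative Holt-Winters is undefined for non-positive ",
         "values; shortage sentinels must be imputed first")
  st <- init_level_trend(y, init, init_values, init_m,
                         default = if (trend) "ols_on_first_m"
                                   else "first_observation")
  a <- st$level
  b <- if (trend) st$trend else 0
  neutral <- if (seasonal == "additive") 0 else 1
  cs_init <- rep(neutral, P)
  if (init == "explicit" && !is.null(init_values$seasonal)) {
    if (length(init_values$seasonal) != P)
      stop("explicit seasonal init must have length period = ", P)
    cs_init <- as.numeric(init_values$seasonal)
  }
  # cs[j + off] holds the factor for week j, j in (2-P)..t_n
  off <- P - 1L
  cs <- c(cs_init, rep(NA_real_, t_n - 1L))
  fitted <- rep(NA_real_, t_n)
  for (t in 2L:t_n) {
    cprev <- cs[t - P + off]
    fitted[t] <- if (seasonal == "additive") a + b + cprev
                 else (a + b) * cprev
    a_prev <- a
    a <- if (seasonal == "additive")
      alpha * (y[t] - cprev) + (1 - alpha) * (a_prev + b)
    else
      alpha * (y[t] / cprev) + (1 - alpha) * (a_prev + b)
    if (trend) b <- beta * (a - a_prev) + (1 - beta) * b
    cs[t + off] <- if (seasonal == "additive")
      gamma * (y[t] - a) + (1 - gamma) * cprev
    else
      gamma * (y[t] / a) + (1 - gamma) * cprev
  }
  future <- vapply(seq_len(h), function(k) {
    j <- t_n + k - P * ceiling(k / P)    # most recent factor for that season
    ck <- cs[j + off]
    if (seasonal == "additive") a + k * b + ck else (a + k * b) * ck
  }, numeric(1))
  list(fitted = fitted, future = future,
       components = list(level = a, trend = if (trend) b else NULL,
                         seasonal = cs[(t_n - P + 1L):t_n + off]),
       state = list(kind = "seasonal", level = a, trend = b,
                    seasonal = cs, offset = off, t_n = t_n, period = P,
                    form = seasonal))
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.pharma_forecast <- function(x, ...) {
  t_n <- length(x$series$values)
  cat("Weekly sales forecast (", x$method, ") for series '",
      x$series$series_id, "'\n", sep = "")
  cat("  ", t_n, " weeks fitted (", sum(!is.na(x$fitted)),
      " evaluated, warm-up ", sum(is.na(x$fitted)), "), horizon ",
      length(x$future), "\n", sep = "")
  cat("  next-week forecast: ", format(x$future[1L]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.pharma_forecast <- function(object, ...) {
  res <- residuals(object)
  out <- list(method = object$method, series_id = object$series$series_id,
              n = length(object$series$values),
              n_eval = sum(!is.na(object$fitted)),
              components = object$components,
              residual_summary = summary(res[!is.na(res)]),
              future = object$future)
  class(out) <- "summary.pharma_forecast"
  out
}

#' @export
print.summary.pharma_forecast <- function(x, ...) {
  cat("Method:", x$method, " series:", x$series_id, "\n")
  cat("Weeks:", x$n, " evaluated one-step forecasts:", x$n_eval, "\n")
  cat("Final components:\n")
  for (nm in names(x$components)) if (!is.null(x$components[[nm]]))
    cat("  ", nm, ": ", paste(format(x$components[[nm]], digits = 6),
                              collapse = " "), "\n", sep = "")
  cat("One-step residuals:\n")
  print(x$residual_summary)
  cat("Future forecasts:", paste(format(x$future, digits = 6),
                                 collapse = " "), "\n")
  invisible(x)
}

#' @export
fitted.pharma_forecast <- function(object, ...) object$fitted

#' @export
residuals.pharma_forecast <- function(object, ...)
  object$series$values - object$fitted

#' @export
coef.pharma_forecast <- function(object, ...) {
  cmp <- object$components
  out <- c(level = cmp$level,
           if (!is.null(cmp$trend)) c(trend = cmp$trend))
  if (!is.null(cmp$seasonal))
    out <- c(out, stats::setNames(cmp$seasonal,
                                  paste0("seasonal", seq_along(cmp$seasonal))))
  out
}

#' Forecast future weeks from a fitted model
#'
#' Extends (or shortens) the future horizon using the stored final state;
#' the recursion is not re-run.
#'
#' @param object A `pharma_forecast`.
#' @param horizon Number of future weeks. Defaults to the fitted horizon.
#' @param ... Unused.
#' @return Numeric vector of forecasts for weeks t+1 .. t+horizon.
#' @export
predict.pharma_forecast <- function(object, horizon = NULL, ...) {
  if (is.null(horizon)) return(object$future)
  horizon <- as.integer(horizon)
  stopifnot(horizon >= 1L)
  st <- object$state
  k <- seq_len(horizon)
  switch(st$kind,
    level = rep(st$level, horizon),
    linear = st$level + k * st$trend,
    combined = Reduce(`+`, lapply(st$members, predict, horizon = horizon)),
    seasonal = vapply(k, function(kk) {
      j <- st$t_n + kk - st$period * ceiling(kk / st$period)
      ck <- st$seasonal[j + st$offset]
      if (st$form == "additive") st$level + kk * st$trend + ck
      else (st$level + kk * st$trend) * ck
    }, numeric(1)))
}

#' @export
plot.pharma_forecast <- function(x, ...) {
  y <- x$series$values
  wk <- x$series$weeks
  h <- length(x$future)
  xlim <- c(1, max(wk) + h)
  ylim <- range(c(y, x$fitted, x$future), na.rm = TRUE)
  graphics::plot(wk, y, type = "b", pch = 16, xlim = xlim, ylim = ylim,
                 xlab = "week", ylab = "quantity",
                 main = paste0("'", x$series$series_id, "' - ", x$method),
                 ...)
  graphics::lines(wk, x$fitted, col = "steelblue", lty = 2)
  graphics::points(max(wk) + seq_len(h), x$future, col = "firebrick",
                   pch = 17)
  invisible(x)
}

# ---- demand-driven forecast ------------------------------------------------

#' Demand-driven (patient-based) forecast
#'
#' For prescription drugs with a known patient base, next-week sales can be
#' forecast as the product of the expected number of patients visiting the
#' pharmacy, the drug's penetration (the fraction of prescribed patients who
#' purchase it) and the average quantity per purchase.
#'
#' @param patients_forecast Expected number of patients (non-negative).
#' @param penetration Fraction in [0, 1].
#' @param avg_quantity Average units per purchasing patient (non-negative).
#' @return Forecast sales quantity, `patients_forecast * penetration *
#'   avg_quantity`.
#' @examples
#' demand_driven_forecast(100, 0.2, 3) # 60 units
#' @export
demand_driven_forecast <- function(patients_forecast, penetration,
                                   avg_quantity) {
  if (patients_forecast < 0 || avg_quantity < 0 || penetration < 0)
    stop("demand_driven_forecast: inputs must be non-negative")
  if (penetration > 1)
    stop("demand_driven_forecast: penetration must be in [0, 1]")
  patients_forecast * penetration * avg_quantity
}
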