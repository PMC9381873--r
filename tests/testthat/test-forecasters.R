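chain13 <- example_chain_sales("steady")

test_that("naive forecaster repeats the last observation", {
  f <- pharma_forecast(chain13, "naive")
  expect_true(is.na(fitted(f)[1]))
  expect_equal(fitted(f)[2], 21819)
  expect_equal(fitted(f)[-1], chain13$values[-13])

  const <- pharma_forecast(c(5, 5, 5), "naive")
  expect_equal(fitted(const)[-1], c(5, 5))

  f2 <- pharma_forecast(c(10, 20), "naive",
                        params = smoothing_params(horizon = 3))
  expect_equal(fitted(f2)[2], 10)
  expect_equal(f2$future, c(20, 20, 20))
})

test_that("moving average uses the trailing window and repeats it ahead", {
  f <- pharma_forecast(chain13, "moving_average")
  expect_equal(which(is.na(fitted(f))), 1:2)
  expect_equal(fitted(f)[11], (18986 + 24854) / 2)  # = 21920
  expect_equal(fitted(f)[11], 21920)

  f3 <- pharma_forecast(c(2, 4, 6), "moving_average",
                        params = smoothing_params(window = 2))
  expect_equal(fitted(f3)[3], 3)
  expect_equal(f3$future[1], 5)

  w1 <- pharma_forecast(chain13, "moving_average",
                        params = smoothing_params(window = 1))
  nv <- pharma_forecast(chain13, "naive")
  expect_equal(fitted(w1)[-1], fitted(nv)[-1])

  expect_error(pharma_forecast(c(1, 2, 3), "moving_average",
                               params = smoothing_params(window = 3)),
               "window")
})

test_that("single exponential smoothing with F2 = Y1 initialization", {
  f <- pharma_forecast(chain13, "ses")
  expect_equal(fitted(f)[2], 21819)
  expect_equal(fitted(f)[3], 0.2 * 22344 + 0.8 * 21819)  # = 21924
  expect_equal(fitted(f)[3], 21924)
  expect_equal(fitted(f), oracle_ses(chain13$values, 0.2))

  a1 <- pharma_forecast(chain13, "ses", params = smoothing_params(alpha = 1))
  nv <- pharma_forecast(chain13, "naive")
  expect_equal(fitted(a1), fitted(nv))

  f2 <- pharma_forecast(c(10, 20), "ses",
                        params = smoothing_params(alpha = 0.5))
  expect_equal(fitted(f2)[2], 10)
  expect_equal(f2$future[1], 15)
})

test_that("Holt's linear trend recursion and initialization rules", {
  f <- pharma_forecast(c(12, 14, 17), "holt_linear",
                       params = smoothing_params(alpha = 0.4, beta = 0.7),
                       init = "explicit",
                       init_values = list(level = 12, trend = 2))
  expect_equal(fitted(f)[2], 14)
  expect_equal(fitted(f)[3], 16)  # a2 = 14, b2 = 2 by hand

  # an exactly linear series is a fixed point under the default OLS init
  y <- 100 + 10 * (1:10)
  fl <- pharma_forecast(y, "holt_linear",
                        params = smoothing_params(alpha = 0.4, beta = 0.7,
                                                  horizon = 4))
  expect_equal(fitted(fl)[-1], y[-1])
  expect_equal(fl$future, y[10] + 10 * (1:4))
  expect_equal(unname(coef(fl)[["trend"]]), 10)

  # beta = 0 with zero starting trend freezes the trend: SES with same alpha
  set.seed(21)
  y2 <- random_positive_series(12)
  h0 <- pharma_forecast(y2, "holt_linear",
                        params = smoothing_params(alpha = 0.3, beta = 0),
                        init = "first_observation")
  s0 <- pharma_forecast(y2, "ses", params = smoothing_params(alpha = 0.3))
  expect_equal(fitted(h0), fitted(s0))

  expect_error(pharma_forecast(c(1, 2), "holt_linear"), "at least 3")
})

test_that("Holt-Winters no-trend reduces to SES when seasonality is frozen", {
  flat <- pharma_forecast(rep(40, 8), "hw_no_trend")
  expect_equal(fitted(flat)[-1], rep(40, 7))
  expect_equal(flat$future, 40)

  set.seed(31)
  y <- random_positive_series(13)
  hw <- pharma_forecast(y, "hw_no_trend",
                        params = smoothing_params(alpha = 0.2, gamma = 0))
  s <- pharma_forecast(y, "ses", params = smoothing_params(alpha = 0.2))
  expect_equal(fitted(hw), fitted(s))

  # a pure period-2 cycle with exact starting state continues exactly
  cyc <- pharma_forecast(c(10, 20, 10, 20), "hw_no_trend",
                         params = smoothing_params(alpha = 0.2, gamma = 0.05,
                                                   period = 2, horizon = 2),
                         init = "explicit",
                         init_values = list(level = 15,
                                            seasonal = c(5, -5)))
  expect_equal(fitted(cyc)[-1], c(20, 10, 20))
  expect_equal(cyc$future, c(10, 20))

  expect_error(pharma_forecast(c(1, 2), "hw_no_trend",
                               params = smoothing_params(period = 2)),
               "period")
})

test_that("additive Holt-Winters: hand step, degeneracy, fixed point", {
  f <- pharma_forecast(c(10, 12), "hw_additive",
                       params = smoothing_params(alpha = 0.2, beta = 0.15,
                                                 gamma = 0),
                       init = "explicit",
                       init_values = list(level = 10, trend = 2,
                                          seasonal = 0))
  expect_equal(fitted(f)[2], 12)
  expect_equal(unname(coef(f)[["level"]]), 12)  # a2 = 0.2*12 + 0.8*12

  set.seed(41)
  y <- random_positive_series(13)
  hw <- pharma_forecast(y, "hw_additive",
                        params = smoothing_params(alpha = 0.4, beta = 0.7,
                                                  gamma = 0))
  hl <- pharma_forecast(y, "holt_linear",
                        params = smoothing_params(alpha = 0.4, beta = 0.7))
  expect_equal(fitted(hw), fitted(hl))

  # linear trend + additive period-3 cycle with exact init continues exactly
  seas <- c(4, -9, 5)
  y3 <- 50 + 2 * (1:12) + rep(seas, 4)
  fx <- pharma_forecast(y3, "hw_additive",
                        params = smoothing_params(alpha = 0.2, beta = 0.15,
                                                  gamma = 0.05, period = 3,
                                                  horizon = 6),
                        init = "explicit",
                        init_values = list(level = 52, trend = 2,
                                           seasonal = c(-9, 5, 4)))
  expect_equal(fitted(fx)[-1], y3[-1])
  expect_equal(fx$future, 50 + 2 * (13:18) + rep(seas, 2))
})

test_that("multiplicative Holt-Winters: degeneracy, fixed point, domain", {
  set.seed(51)
  y <- random_positive_series(13)
  hm <- pharma_forecast(y, "hw_multiplicative",
                        params = smoothing_params(alpha = 0.4, beta = 0.7,
                                                  gamma = 0))
  hl <- pharma_forecast(y, "holt_linear",
                        params = smoothing_params(alpha = 0.4, beta = 0.7))
  expect_equal(fitted(hm), fitted(hl))

  # multiplicative period-2 cycle around a constant level is a fixed point
  y2 <- 100 * rep(c(0.8, 1.2), 5)
  fx <- pharma_forecast(y2, "hw_multiplicative",
                        params = smoothing_params(alpha = 0.2, beta = 0.15,
                                                  gamma = 0.05, period = 2,
                                                  horizon = 4),
                        init = "explicit",
                        init_values = list(level = 100, trend = 0,
                                           seasonal = c(1.2, 0.8)))
  expect_equal(fitted(fx)[-1], y2[-1])
  expect_equal(fx$future, 100 * rep(c(0.8, 1.2), 2))

  expect_error(pharma_forecast(weekly_series(c(5, 0, 4), missing = rep(FALSE, 3)),
                               "hw_multiplicative"),
               "non-positive")
})

test_that("double exponential smoothing: hand step and degeneracies", {
  f <- pharma_forecast(c(10, 20), "double_exp",
                       params = smoothing_params(alpha = 0.2, gamma = 0.15))
  # S1 = 12, S2 = 10.3 by hand
  expect_equal(unname(coef(f)[["level"]]), 13.7)
  expect_equal(f$components$s1, 12)
  expect_equal(f$components$s2, 10.3)

  const <- pharma_forecast(rep(7, 9), "double_exp",
                           params = smoothing_params(alpha = 0.2,
                                                     gamma = 0.15,
                                                     horizon = 3))
  expect_equal(fitted(const)[-1], rep(7, 8))
  expect_equal(const$future, rep(7, 3))
  expect_equal(unname(coef(const)[["trend"]]), 0)

  # gamma = alpha is classical Brown double smoothing
  set.seed(61)
  y <- random_positive_series(13)
  f2 <- pharma_forecast(y, "double_exp",
                        params = smoothing_params(alpha = 0.3, gamma = 0.3))
  br <- oracle_brown(y, 0.3, 0.3)
  expect_equal(fitted(f2), br$fitted)

  expect_error(pharma_forecast(y, "double_exp",
                               params = smoothing_params(alpha = 1,
                                                         gamma = 0.15)),
               "alpha < 1")
})

test_that("every recursion matches its independent oracle on random series", {
  set.seed(71)
  for (rep in 1:20) {
    y <- random_positive_series(sample(8:20, 1))
    n <- length(y)

    expect_equal(fitted(pharma_forecast(y, "naive")), oracle_naive(y))
    w <- sample(1:3, 1)
    expect_equal(fitted(pharma_forecast(y, "moving_average",
                                        params = smoothing_params(window = w))),
                 oracle_ma(y, w), tolerance = 1e-9)
    al <- runif(1, 0.05, 0.95)
    expect_equal(fitted(pharma_forecast(y, "ses",
                                        params = smoothing_params(alpha = al))),
                 oracle_ses(y, al), tolerance = 1e-9)
    be <- runif(1, 0.05, 0.95)
    ho <- oracle_holt(y, al, be, a1 = y[1], b1 = y[2] - y[1])
    expect_equal(fitted(pharma_forecast(y, "holt_linear",
                                        params = smoothing_params(alpha = al,
                                                                  beta = be))),
                 ho$fitted, tolerance = 1e-9)
    ga <- runif(1, 0.05, 0.95)
    expect_equal(fitted(pharma_forecast(y, "double_exp",
                                        params = smoothing_params(alpha = al,
                                                                  gamma = ga))),
                 oracle_brown(y, al, ga)$fitted, tolerance = 1e-9)

    P <- sample(c(1, 4), 1)
    prm <- smoothing_params(alpha = al, beta = be, gamma = ga, period = P)
    expect_equal(
      fitted(pharma_forecast(y, "hw_no_trend", params = prm)),
      oracle_hw(y, al, 0, ga, P, "additive", a1 = y[1], b1 = 0,
                cs0 = rep(0, P))$fitted,
      tolerance = 1e-9)
    expect_equal(
      fitted(pharma_forecast(y, "hw_additive", params = prm)),
      oracle_hw(y, al, be, ga, P, "additive", a1 = y[1], b1 = y[2] - y[1],
                cs0 = rep(0, P))$fitted,
      tolerance = 1e-9)
    expect_equal(
      fitted(pharma_forecast(y, "hw_multiplicative", params = prm)),
      oracle_hw(y, al, be, ga, P, "multiplicative", a1 = y[1],
                b1 = y[2] - y[1], cs0 = rep(1, P))$fitted,
      tolerance = 1e-9)
  }
})

test_that("constant series with matching init is a fixed point of every method", {
  y <- rep(120, 10)
  for (m in forecast_methods()) {
    f <- pharma_forecast(y, m, init = "first_observation",
                         params = {
                           p <- default_method_params(m)
                           p$horizon <- 3L
                           p
                         },
                         init_values = NULL)
    if (m == "hw_multiplicative" || m == "hw_no_trend" || m == "hw_additive") {
      f <- pharma_forecast(y, m, init = "explicit",
                           init_values = list(
                             level = 120, trend = 0,
                             seasonal = if (m == "hw_multiplicative") 1 else 0),
                           params = default_method_params(m, horizon = 3L))
    }
    expect_equal(unname(fitted(f)[-seq_len(sum(is.na(fitted(f))))]),
                 rep(120, 10 - sum(is.na(fitted(f)))), info = m)
    expect_equal(unname(f$future), rep(120, 3), info = m)
    expect_true(all(is.finite(fitted(f)[!is.na(fitted(f))])), info = m)
  }
})

test_that("forecasting refuses series with unimputed shortage weeks", {
  s <- weekly_series(c(10, 0, 12, 14))
  expect_error(pharma_forecast(s, "ses"), "impute")
})

test_that("predict extends the horizon from the stored state", {
  f <- pharma_forecast(chain13, "holt_linear")
  p4 <- predict(f, horizon = 4)
  expect_equal(length(p4), 4)
  expect_equal(p4[1], f$future[1])
  expect_equal(diff(p4), rep(unname(coef(f)[["trend"]]), 3))
  expect_equal(predict(pharma_forecast(chain13, "ses"), horizon = 5),
               rep(f2 <- pharma_forecast(chain13, "ses")$future[1], 5))
})

test_that("demand-driven forecast multiplies patients, penetration, quantity", {
  expect_equal(demand_driven_forecast(0, 0.5, 10), 0)
  expect_equal(demand_driven_forecast(100, 0.2, 3), 60)
  expect_equal(demand_driven_forecast(1, 1, 7.5), 7.5)
  expect_error(demand_driven_forecast(-1, 0.5, 1), "non-negative")
  expect_error(demand_driven_forecast(10, 1.5, 1), "penetration")
})
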