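# Independent, deliberately naive re-implementations of every recursion,
# written as explicit component-storing loops. These are the oracles the
# package engines are checked against; they share no code with R/.

oracle_naive <- function(y) {
  n <- length(y)
  fitted <- rep(NA_real_, n)
  for (t in 2:n) fitted[t] <- y[t - 1]
  fitted
}

oracle_ma <- function(y, w) {
  n <- length(y)
  fitted <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t > w) {
      acc <- 0
      for (j in (t - w):(t - 1)) acc <- acc + y[j]
      fitted[t] <- acc / w
    }
  }
  fitted
}

oracle_ses <- function(y, alpha) {
  n <- length(y)
  F <- rep(NA_real_, n)
  F[2] <- y[1]
  for (t in 2:(n - 1)) F[t + 1] <- alpha * y[t] + (1 - alpha) * F[t]
  F
}

oracle_holt <- function(y, alpha, beta, a1, b1) {
  n <- length(y)
  a <- rep(NA_real_, n); b <- rep(NA_real_, n)
  a[1] <- a1; b[1] <- b1
  fitted <- rep(NA_real_, n)
  for (t in 2:n) {
    fitted[t] <- a[t - 1] + b[t - 1]
    a[t] <- alpha * y[t] + (1 - alpha) * (a[t - 1] + b[t - 1])
    b[t] <- beta * (a[t] - a[t - 1]) + (1 - beta) * b[t - 1]
  }
  list(fitted = fitted, a = a, b = b)
}

oracle_brown <- function(y, alpha, gamma) {
  n <- length(y)
  s1 <- rep(NA_real_, n); s2 <- rep(NA_real_, n)
  s1[1] <- y[1]; s2[1] <- y[1]
  fitted <- rep(NA_real_, n)
  for (t in 2:n) {
    lev <- 2 * s1[t - 1] - s2[t - 1]
    tr <- (alpha / (1 - alpha)) * (s1[t - 1] - s2[t - 1])
    fitted[t] <- lev + tr
    s1[t] <- alpha * y[t] + (1 - alpha) * s1[t - 1]
    s2[t] <- gamma * s1[t] + (1 - gamma) * s2[t - 1]
  }
  list(fitted = fitted,
       level = 2 * s1[n] - s2[n],
       trend = (alpha / (1 - alpha)) * (s1[n] - s2[n]))
}

# seasonal factors indexed by week; cs0 covers weeks (2-P)..1, oldest first
oracle_hw <- function(y, alpha, beta, gamma, P, form, a1, b1, cs0) {
  n <- length(y)
  cs <- c(cs0, rep(NA_real_, n - 1))    # position j + (P-1) is week j
  off <- P - 1
  a <- a1; b <- b1
  fitted <- rep(NA_real_, n)
  for (t in 2:n) {
    cp <- cs[t - P + off]
    if (form == "additive") {
      fitted[t] <- a + b + cp
      anew <- alpha * (y[t] - cp) + (1 - alpha) * (a + b)
    } else {
      fitted[t] <- (a + b) * cp
      anew <- alpha * (y[t] / cp) + (1 - alpha) * (a + b)
    }
    bnew <- beta * (anew - a) + (1 - beta) * b
    cs[t + off] <- if (form == "additive")
      gamma * (y[t] - anew) + (1 - gamma) * cp
    else gamma * (y[t] / anew) + (1 - gamma) * cp
    a <- anew; b <- bnew
  }
  list(fitted = fitted, a = a, b = b, cs = cs)
}

# random strictly positive series for property tests
random_positive_series <- function(n = 13, mean = 300, sd = 60) {
  abs(rnorm(n, mean, sd)) + 1
}

# a series with exactly the requested observed mean/sd plus missing weeks
series_with_stats <- function(m, s, n_obs, missing_weeks, id = "x") {
  base <- seq_len(n_obs)
  v <- m + s * (base - mean(base)) / sd(base)
  n <- n_obs + length(missing_weeks)
  vals <- rep(0, n)
  vals[setdiff(seq_len(n), missing_weeks)] <- v
  weekly_series(vals, series_id = id)
}

make_panel <- function(...) {
  chain_panel(list(...))
}
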