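---
title: "Forecasting weekly pharmacy-chain drug sales: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting weekly pharmacy-chain drug sales: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmacast)
```

## The problem

A retail pharmacy chain must decide each week how much of each drug to
order. Two features make the historical sales record treacherous as a
forecasting input. First, **stockouts**: when a drug is unavailable, the
week records a sentinel (0, or 0.0001 in some bookkeeping systems) rather
than true demand, and the following *recovery week* is inflated by pent-up
purchases. Second, **panic buying**: a single week of extraordinary
demand — typical for a popular product just after a shortage — that any
extrapolative method will chase. Forecasting from such a record without
cleaning systematically over- or under-supplies.

A second question is the **planning level**. The chain can forecast its
aggregated total $Y_t = \sum_{i=1}^{n} Y_i(t)$ and allocate down, or
forecast every pharmacy $Y_i(t)$ separately and sum the forecasts,
$Y_{t+\tau} = \sum_i Y_i(t+\tau)$. The package operationalizes both,
each with and without outlier response — four approaches, run by
`run_approach()` — and selects among eight forecasting methods by a
relative-accuracy criterion.

The reference setting throughout is a chain of $n = 8$ pharmacies
observed for $T = 13$ weeks (one quarter, chosen to match the longest
supplier lead time), forecasting one week ahead ($\tau = 1$).

## Forecasting methods

All eight methods are fitted by `pharma_forecast()` and share one
convention: `fitted[t]` is the forecast of week $t$ made from the state
after week $t-1$; weeks a method cannot forecast (its *warm-up*) are
`NA` — week 1 for the recursive methods, weeks $1..w$ for a window-$w$
moving average. Fixed default parameters (see
`default_method_params()`):

| method | recursion | defaults |
|---|---|---|
| naive | $\hat Y_{t+1} = Y_t$ | — |
| moving_average | $\hat Y_{t+1} = \frac1w\sum_{j=t-w+1}^{t} Y_j$ | $w=2$ |
| ses | $F_{t+1} = \alpha Y_t + (1-\alpha)F_t$ | $\alpha=0.2$ |
| double_exp | $S'_t = \alpha Y_t + (1-\alpha)S'_{t-1}$; $S''_t=\gamma S'_t+(1-\gamma)S''_{t-1}$ | $\alpha=0.2,\ \gamma=0.15$ |
| holt_linear | $a_t = \alpha Y_t + (1-\alpha)(a_{t-1}+b_{t-1})$; $b_t=\beta(a_t-a_{t-1})+(1-\beta)b_{t-1}$ | $\alpha=0.4,\ \beta=0.7$ |
| hw_no_trend | additive seasonal, $b\equiv 0$ | $\alpha=0.2,\ \gamma=0.05$ |
| hw_additive | $a_t=\alpha(Y_t-c_{t-P})+(1-\alpha)(a_{t-1}+b_{t-1})$, $c_t=\gamma(Y_t-a_t)+(1-\gamma)c_{t-P}$ | $\alpha=0.2,\ \beta=0.15,\ \gamma=0.05$ |
| hw_multiplicative | as additive with ratios $Y_t/c_{t-P}$, $Y_t/a_t$ | $\alpha=0.2,\ \beta=0.15,\ \gamma=0.05$ |

The smoothing weights are deliberately small: weekly drug sales fluctuate
around a fairly stable mean, and small weights damp the variance the
forecast inherits from the data. The parameters are treated as fixed
operating constants, not tuned per series — the point of the model is
method and level selection under a common configuration, and optimizing
eight methods per product on 13 points would mostly fit noise.

### Initialization

On a 13-week series the starting state matters, and no choice is
canonical; the package makes it explicit and configurable
(`init` argument):

* **SES** starts with $F_2 = Y_1$. This is the one convention that is
  effectively forced: it makes the week-2 forecast equal the first
  observation and reproduces standard worked examples of the recursion.
* **Trend methods** (Holt's linear, additive and multiplicative
  Holt-Winters) default to `ols_on_first_m` with $m = 2$: the
  least-squares line through the first two observations, i.e.
  $a_1 = Y_1$, $b_1 = Y_2 - Y_1$ — the "average early history" convention
  for trend initialization, reduced to its minimal window.
  `first_observation` ($a_1=Y_1$, $b_1=0$) and `explicit` values are
  available; with $\beta=0$ and a flat start Holt's linear provably
  collapses to SES, which the tests exploit.
* **Seasonal factors** initialize neutrally (0 additive, 1
  multiplicative) unless given explicitly. The seasonal period defaults
  to $P = 1$: a 13-week window of weekly data cannot support an
  estimated annual cycle, and the pandemic-era search data for these
  products show no within-quarter seasonality. Any $P \ge 1$ is
  accepted and fully exercised by the property tests.
* **Double smoothing** starts $S'_1 = S''_1 = Y_1$. This method is
  described in the field both as a seasonal technique and with Brown's
  two-pass equations; the package implements the two-pass reading with
  *separate* weights ($\alpha$ for the first pass, $\gamma$ for the
  second) and keeps Brown's trend factor $\frac{\alpha}{1-\alpha}(S'-S'')$.
  With $\gamma=\alpha$ it is exactly classical Brown smoothing (tested
  against an independent oracle). $\alpha = 1$ is rejected (degenerate
  trend denominator).

Forecasts are reported as computed, including negative values that the
trend methods can produce after a deep stockout; flooring at zero is the
planner's decision, and the approach runner flags such weeks
(`negative_forecast_weeks`) instead of silently truncating.

## Cleaning

**Imputation** (`impute_missing()`) replaces every shortage week with the
arithmetic mean of the observed weeks. This keeps the series mean exactly
and shrinks the sample standard deviation by
$\sqrt{(n_1-1)/(N-1)}$ ($n_1$ observed of $N$ weeks) — a law the tests
verify for all eight reference pharmacies (e.g. an s.d. of 82.99 over 10
observed weeks becomes $82.99\sqrt{9/12} = 71.87$ over 13). Imputation is
deliberately simple: on a 13-week horizon anything model-based would
borrow strength the data do not have.

**Outlier detection** (`detect_outlier()`) is the two-tailed
single-outlier Grubbs test: $G = \max_i |Y_i - \bar Y|/s$ with the
sample ($N-1$) standard deviation, against
$G_{crit} = \frac{N-1}{\sqrt N}\sqrt{\frac{t^2}{N-2+t^2}}$, $t$ the
upper $\alpha/(2N)$ quantile of Student's $t$ on $N-2$ d.f.
($G_{crit}(13, 0.05) = 2.4620$). The decision rule is the standard one
— $G > G_{crit}$ flags an outlier; descriptions of the test sometimes
state the inequality the other way round, so both $G$ and $G_{crit}$ are
exposed and the user can apply any rule. The test runs single-pass (one
outlier per series per run), ties at the maximum deviation go to the
earliest week, a zero-variance series is an error, and running the test
on an unimputed series is refused: sentinels would dominate the
statistic, so the pipeline order impute → detect → replace is enforced.

**Replacement** (`replace_outlier()`) winsorizes the flagged point to
$\bar Y \pm 3s$ computed *excluding* it, pulling the week inside the
healthy distribution while preserving its direction; replacing with the
plain mean is available as a policy switch. Every action — imputations
and replacements — lands in a `cleaning_report` audit table.

## Accuracy and selection

Three criteria, computed by `evaluate_forecast()` over the weeks each
method actually forecasts:

$$\mathrm{MAPE} = \frac{100}{t}\sum \frac{|Y - \hat Y|}{Y}, \qquad
\mathrm{MSE} = \frac1t\sum (\hat Y - Y)^2, \qquad
U_2 = \frac{\mathrm{MSE(method)}}{\mathrm{MSE(naive)}}.$$

Two conventions deserve emphasis. First, the evaluation windows follow
the warm-ups and are **not** forced to a common set: on 13 weeks the
naive and SES forecasts are scored over 12 weeks but the window-2 moving
average over 11. This matches how such tables are conventionally
computed; `common_window = TRUE` gives the statistically cleaner
intersection-window comparison. Second, $U_2$ here is the plain MSE
ratio, not the square-rooted textbook Theil statistic — values below 1
mean the method beats the naive benchmark, and selection
(`select_best()`) takes the argmin with registry-order tie-breaks,
falling back to naive whenever nothing beats it. MAPE is reported for
reference but does not drive selection; on series still containing
sentinels it explodes by construction (division by a near-zero actual),
which is why `mape()` refuses sentinel actuals unless explicitly told
otherwise.

Display rounding mirrors conventional reporting (MAPE 2 d.p., MSE
integer, $U_2$ 5 d.p.); stored values keep full precision.

## The approaches in detail

Approach 1 forecasts the raw aggregate, sentinels included — the chain
total of a stocked-out week is (close to) zero and the methods see it.
This is the honest baseline: on shortage products it is typically won by
the naive method, because every smoother drags the stockout crater into
subsequent forecasts. The aggregate of a panel keeps a week flagged as
missing only when *every* pharmacy was out (`missing_rule = "all"`);
with `keep_sentinels = TRUE` (what approach 1 uses) nothing is flagged
and the raw sums stand.

Approach 2 cleans the aggregate first. Approaches 3–4 work per pharmacy
and sum forecasts; for the linear recursions with shared parameters and
init (naive, SES, moving average) summation commutes with fitting, so
approaches 3 and 1 agree exactly — a strong cross-module invariant the
tests assert to $10^{-9}$. The seasonal/trend methods are nonlinear in
the data, and the disaggregated fit genuinely differs: that difference
is the point of hierarchical planning.

By default approaches 3–4 evaluate the summed forecasts against the
**raw** aggregated actuals, so $U_2$ measures real predictive quality
rather than fit to an edited series; `evaluate_on_cleaned = TRUE`
switches to the cleaned aggregate, which is the more flattering (and in
published comparisons more common) convention. A method whose recursion
is undefined on the data at hand — the multiplicative form on
zero-sentinel sums — is skipped and reported, not fatal.

`safety_stock_uplift()` covers the complementary planning rule for
categories with known year-on-year growth (e.g. +6% alimentary, +4%
respiratory, +1% cardiovascular, +10% dermatological): a historical
forecast is raised by the growth rate as safety stock.

## The synthetic panel generator

`generate_chain()` emulates the reference study conditions so every
pipeline stage is testable without any external data: 8 pharmacies ×
13 weeks; weekly demand i.i.d. Normal(mean, sd) per pharmacy —
the working distributional assumption for these products — truncated at
zero by resampling (clipping would pile mass at zero and masquerade as
shortage); per-pharmacy means 249–320 units/week and s.d.s 55–128
calibrated to a real shortage-prone product
(`default_chain_specs()`); chain-wide stockout runs of two shortage
weeks plus one distorted week (weeks 8–10; the eighth pharmacy recovers
a week earlier); optional panic-buying spikes injected at
$\mu + k\sigma$ (default $k = 6$). Per-series seeds are derived from the
base seed plus a stable hash of the pharmacy id, so extending a panel
never perturbs existing series.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: cross-pharmacy correlation
(real panic buying hits all pharmacies at once; the generator draws
independently), within-quarter trends or seasonality, autocorrelated
demand, and recovery-week dynamics beyond a single distorted value.
Conclusions about which approach wins on real chains should rest on the
structural invariants (aggregation identities, cleaning laws), which
hold regardless, not on simulated accuracy rankings.

## Numerical and testing choices

* Week indices are 1-based and consecutive; all containers validate this
  and name the offending series and week on failure.
* Sentinel threshold: any quantity $\le$ 0.001 is a shortage sentinel
  (covers both 0 and 0.0001); raw values are preserved for audit.
  Negative quantities are rejected outright.
* Test problem sizes: property tests run 20 random series per recursion
  (lengths 8–20), 200 seeded replicates for the outlier-detection-rate
  check, and 50–60 replicates for parameter recovery — large enough for
  the stated sampling bounds ($3\sigma/\sqrt{n}$) while keeping the
  whole suite in a few seconds.
* The oracles in the test suite are independent plain-loop
  re-implementations of every recursion, compared at $10^{-9}$; the
  Grubbs critical value is frozen against an externally computed
  t-quantile.

## Known limitations

Thirteen weekly points support neither parameter optimization nor
estimated seasonality; the package accordingly fixes both and says so.
The Grubbs test assumes approximate normality and tests a single
outlier; for multiple contaminated weeks an iterative or ESD-type
procedure would be needed. Mean imputation flattens stockout weeks to
the series mean, which understates recovery-week dynamics. And $U_2$
selection on a single 13-week series has substantial variance: the
selected method is the best *on this window*, not a verdict about the
product.
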