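#' Specification for one synthetic pharmacy
#'
#' Parameters for generating one pharmacy's weekly sales: demand is drawn
#' from a normal distribution (the working assumption for weekly drug
#' demand) truncated at zero, with optional shortage weeks (set to the
#' sentinel) and an optional single-week panic-buying spike placed at
#' `mean + outlier_multiplier * sd`.
#'
#' @param series_id Pharmacy label.
#' @param mean Mean weekly demand (units/week), non-negative.
#' @param sd Standard deviation of weekly demand, non-negative.
#' @param weeks Number of weeks. Default 13 (one quarter).
#' @param shortage_weeks Integer week indices recorded as stockouts.
#' @param outlier_week Optional week index receiving the spike.
#' @param outlier_multiplier Spike size in sd units. Default 6.
#' @param sentinel Value recorded for shortage weeks. Default 0.
#' @return An object of class `pharmacy_spec`.
#' @export
pharmacy_spec <- function(series_id, mean, sd, weeks = 13L,
                          shortage_weeks = integer(0), outlier_week = NULL,
                          outlier_multiplier = 6, sentinel = 0) {
  weeks <- as.integer(weeks)
  shortage_weeks <- as.integer(shortage_weeks)
  if (mean < 0 || sd < 0) stop("pharmacy_spec: mean and sd must be >= 0")
  if (weeks < 1L) stop("pharmacy_spec: weeks must be positive")
  if (length(shortage_weeks) &&
      (min(shortage_weeks) < 1L || max(shortage_weeks) > weeks))
    stop("pharmacy_spec: shortage weeks out of range for '", series_id, "'")
  if (!is.null(outlier_week)) {
    outlier_week <- as.integer(outlier_week)
    if (outlier_week < 1L || outlier_week > weeks)
      stop("pharmacy_spec: outlier week out of range for '", series_id, "'")
    if (outlier_week %in% shortage_weeks)
      stop("pharmacy_spec: outlier week collides with a shortage week")
  }
  structure(list(series_id = as.character(series_id), mean = mean, sd = sd,
                 weeks = weeks, shortage_weeks = shortage_weeks,
                 outlier_week = outlier_week,
                 outlier_multiplier = outlier_multiplier,
                 sentinel = sentinel),
            class = "pharmacy_spec")
}

# run code under a local, seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# stable, platform-independent hash of a series id (below 2^31)
stable_id_hash <- function(id) {
  codes <- utf8ToInt(id)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003
  as.integer(h)
}

#' Generate one synthetic pharmacy series
#'
#' Weekly demand is Normal(mean, sd) truncated at zero by resampling
#' (clipping would pile mass at 0 and masquerade as shortage). Shortage
#' weeks are then overwritten with the sentinel and the optional spike is
#' placed deterministically at `mean + multiplier * sd`. Identical seeds
#' give identical series.
#'
#' @param spec A [pharmacy_spec()].
#' @param seed Integer seed.
#' @return A [weekly_series()].
#' @export
generate_pharmacy <- function(spec, seed) {
  stopifnot(inherits(spec, "pharmacy_spec"))
  vals <- with_local_seed(seed, {
    v <- stats::rnorm(spec$weeks, spec$mean, spec$sd)
    bad <- which(v < 0)
    guard <- 0L
    while (length(bad)) {
      v[bad] <- stats::rnorm(length(bad), spec$mean, spec$sd)
      bad <- which(v < 0)
      guard <- guard + 1L
      if (guard > 1000L) {  # pathological spec (mean << 0 impossible here)
        v[bad] <- 0
        break
      }
    }
    v
  })
  if (!is.null(spec$outlier_week))
    vals[spec$outlier_week] <- spec$mean + spec$outlier_multiplier * spec$sd
  if (length(spec$shortage_weeks))
    vals[spec$shortage_weeks] <- spec$sentinel
  weekly_series(vals, series_id = spec$series_id)
}

#' Generate a synthetic pharmacy-chain panel
#'
#' Pharmacies are generated independently; each series gets its own seed
#' derived from the base seed plus a stable hash of its id, so adding a
#' pharmacy to the spec list never perturbs the existing series. Real
#' chains may show cross-pharmacy correlation (chain-wide panic buying);
#' the generator deliberately assumes independence.
#'
#' @param specs List of [pharmacy_spec()] sharing one week count.
#' @param seed Integer base seed.
#' @return A [chain_panel()].
#' @examples
#' p <- generate_chain(default_chain_specs(), seed = 42)
#' p$n
#' @export
generate_chain <- function(specs, seed) {
  if (inherits(specs, "pharmacy_spec")) specs <- list(specs)
  if (!length(specs)) stop("generate_chain: no specs")
  wk <- vapply(specs, function(s) s$weeks, integer(1))
  if (length(unique(wk)) != 1L)
    stop("generate_chain: specs disagree on the number of weeks")
  chain_panel(lapply(specs, function(sp)
    generate_pharmacy(sp, seed = (seed + stable_id_hash(sp$series_id)) %%
                        .Machine$integer.max)))
}

#' Default 8-pharmacy chain specification
#'
#' The generator's reference conditions: an 8-pharmacy chain observed for
#' 13 weeks, with per-pharmacy mean/sd calibrated to a real shortage-prone
#' prescription product (means about 250-320 units/week, sds 55-128).
#' With `shortage = TRUE` (default) pharmacies 1-7 carry a 2-week stockout
#' plus a distorted recovery week (weeks 8-10) and pharmacy 8 a 2-week
#' stockout (weeks 8-9), mirroring a chain-wide supply failure.
#'
#' @param shortage Include the stockout runs. Default `TRUE`.
#' @param outlier_week Optional spike week applied to every pharmacy
#'   (e.g. panic buying); `NULL` for none.
#' @param outlier_multiplier Spike size in sd units. Default 6.
#' @return A list of eight [pharmacy_spec()] objects.
#' @export
default_chain_specs <- function(shortage = TRUE, outlier_week = NULL,
                                outlier_multiplier = 6) {
  means <- c(296, 318.4, 306.1, 320.1, 286.1, 286.4, 309.4, 248.7)
  sds <- c(82.99, 64.48, 93.01, 54.66, 77.71, 81.51, 59.42, 128.12)
  lapply(seq_len(8L), function(i) {
    sw <- if (!shortage) integer(0) else if (i < 8L) 8:10 else 8:9
    pharmacy_spec(paste0("pharma", i), means[i], sds[i], weeks = 13L,
                  shortage_weeks = sw, outlier_week = outlier_week,
                  outlier_multiplier = outlier_multiplier)
  })
}

#' Bundled example chain series
#'
#' Two 13-week chain-level (8-pharmacy) weekly sales series for two
#' prescription products, used in the package examples and tests: one
#' with uninterrupted supply (`"steady"`), and one that went through a
#' two-week chain-wide stockout with a distorted recovery week
#' (`"shortage"`; stockout weeks carry the 0.0001 sentinel).
#'
#' @param product `"steady"` or `"shortage"`.
#' @return A [weekly_series()] with `series_id = "chain"`.
#' @examples
#' example_chain_sales("steady")$values[10] # the panic-buying week, 24854
#' @export
example_chain_sales <- function(product = c("steady", "shortage")) {
  product <- match.arg(product)
  vals <- switch(product,
    steady = c(21819, 22344, 20675, 22695, 18226, 19217, 17944, 17799,
               18986, 24854, 16402, 18272, 19393),
    shortage = c(3037, 2910, 2751, 2799, 2375, 2469, 2530, 0.0001, 0.0001,
                 10, 1794, 1449, 1846))
  weekly_series(vals, series_id = "chain")
}
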