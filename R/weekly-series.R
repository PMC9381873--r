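#' Weekly sales series
#'
#' Construct a `weekly_series`, the basic container for one pharmacy's (or
#' the whole chain's) ordered weekly sales quantities. Weeks are abstract
#' 1-based consecutive indices; calendar dates are out of scope. A week whose
#' recorded quantity is at or below `sentinel_epsilon` is flagged as a
#' shortage (stockout) week: the raw value is preserved for audit but the
#' week is treated as missing by the cleaning and forecasting pipeline.
#' Common shortage sentinels in practice are 0 and 0.0001.
#'
#' @param values Numeric vector of non-negative weekly sales quantities
#'   (units sold per week).
#' @param series_id Label for the series (a pharmacy id, or `"chain"`).
#' @param weeks Integer week indices; must be consecutive and start at 1.
#'   Defaults to `seq_along(values)`.
#' @param missing Optional logical vector marking shortage weeks explicitly.
#'   If `NULL` (default), weeks with `values <= sentinel_epsilon` are marked.
#' @param sentinel_epsilon Threshold at or below which a quantity is treated
#'   as a shortage sentinel. Default 0.001 (catches both 0 and 0.0001).
#'
#' @return An object of class `weekly_series`: a list with fields
#'   `series_id`, `weeks`, `values` and `missing_mask`.
#' @examples
#' s <- weekly_series(c(12, 15, 0, 14), series_id = "pharma1")
#' s$missing_mask # week 3 flagged as shortage
#' @export
weekly_series <- function(values, series_id = "series",
                          weeks = seq_along(values), missing = NULL,
                          sentinel_epsilon = 0.001) {
  values <- as.numeric(values)
  weeks <- as.integer(weeks)
  if (length(values) == 0L)
    stop("weekly_series: 'values' must be non-empty")
  if (length(weeks) != length(values))
    stop("weekly_series: 'weeks' and 'values' lengths differ for series '",
         series_id, "'")
  if (weeks[1L] != 1L || any(diff(weeks) != 1L))
    stop("weekly_series: weeks must be consecutive starting at 1 for series '",
         series_id, "' (got gap or offset near week ",
         weeks[which(c(weeks[1L] != 1L, diff(weeks) != 1L))[1L]], ")")
  if (anyNA(values))
    stop("weekly_series: NA quantities are not allowed (series '",
         series_id, "'); use the shortage sentinel instead")
  if (any(values < 0))
    stop("weekly_series: negative quantity in series '", series_id,
         "' at week ", weeks[which(values < 0)[1L]])
  if (is.null(missing)) {
    missing <- values <= sentinel_epsilon
  } else {
    missing <- as.logical(missing)
    if (length(missing) != length(values))
      stop("weekly_series: 'missing' length mismatch for series '",
           series_id, "'")
  }
  structure(
    list(series_id = as.character(series_id), weeks = weeks,
         values = values, missing_mask = missing),
    class = "weekly_series")
}

#' @export
print.weekly_series <- function(x, ...) {
  cat("Weekly sales series '", x$series_id, "': ", length(x$values),
      " weeks, ", sum(x$missing_mask), " shortage week(s)\n", sep = "")
  print(stats::setNames(x$values, paste0("w", x$weeks)))
  invisible(x)
}

#' @export
length.weekly_series <- function(x) length(x$values)

#' @export
as.data.frame.weekly_series <- function(x, ...) {
  data.frame(pharmacy_id = x$series_id, week = x$weeks,
             quantity = x$values, missing = x$missing_mask,
             stringsAsFactors = FALSE)
}

as_weekly_series <- function(x, series_id = "series") {
  if (inherits(x, "weekly_series")) return(x)
  if (is.numeric(x)) return(weekly_series(x, series_id = series_id))
  stop("expected a weekly_series or a numeric vector")
}

#' Pharmacy-chain panel
#'
#' Bundle several [weekly_series()] sharing one week index into a
#' `chain_panel` (n pharmacies x t weeks).
#'
#' @param series A list of `weekly_series` objects covering identical weeks.
#' @return An object of class `chain_panel` with fields `pharmacies`
#'   (named list of series), `n` and `weeks`.
#' @seealso [build_panel()] for construction from long-format records,
#'   [aggregate_chain()] for the chain-level sum.
#' @export
chain_panel <- function(series) {
  if (!length(series)) stop("chain_panel: empty panel")
  series <- lapply(series, as_weekly_series)
  wk <- series[[1L]]$weeks
  for (s in series) {
    if (!identical(s$weeks, wk))
      stop("chain_panel: series '", s$series_id,
           "' does not share the common week range 1..", max(wk))
  }
  ids <- vapply(series, function(s) s$series_id, character(1))
  if (anyDuplicated(ids))
    stop("chain_panel: duplicated series id '", ids[duplicated(ids)][1L], "'")
  names(series) <- ids
  structure(list(pharmacies = series, n = length(series), weeks = wk),
            class = "chain_panel")
}

#' @export
print.chain_panel <- function(x, ...) {
  cat("Pharmacy chain panel: n =", x$n, "pharmacies x t =",
      length(x$weeks), "weeks\n")
  for (s in x$pharmacies)
    cat("  ", format(s$series_id, width = 12), " shortage weeks: ",
        if (any(s$missing_mask)) paste(s$weeks[s$missing_mask],
                                       collapse = ", ") else "none",
        "\n", sep = "")
  invisible(x)
}

#' Build a panel from long-format sales records
#'
#' Validates and assembles long-format records (one row per pharmacy-week)
#' into a [chain_panel()]. Quantities at or below `sentinel_epsilon`
#' (default: catches the sentinels 0 and 0.0001 used to record stockout
#' weeks) are flagged as missing while the raw value is preserved.
#'
#' @param records A data.frame with columns `pharmacy_id`, `week`,
#'   `quantity` (extra columns are ignored).
#' @param sentinel_epsilon Shortage sentinel threshold, see [weekly_series()].
#' @return A `chain_panel`.
#' @examples
#' rec <- expand.grid(pharmacy_id = c("a", "b"), week = 1:3)
#' rec$quantity <- c(1, 10, 2, 20, 3, 30)
#' build_panel(rec)
#' @export
build_panel <- function(records, sentinel_epsilon = 0.001) {
  need <- c("pharmacy_id", "week", "quantity")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("build_panel: records lack column(s): ", paste(miss, collapse = ", "))
  records$pharmacy_id <- as.character(records$pharmacy_id)
  ids <- unique(records$pharmacy_id)
  series <- lapply(ids, function(id) {
    r <- records[records$pharmacy_id == id, , drop = FALSE]
    r <- r[order(r$week), , drop = FALSE]
    if (anyDuplicated(r$week))
      stop("build_panel: duplicated week ",
           r$week[duplicated(r$week)][1L], " for series '", id, "'")
    weekly_series(r$quantity, series_id = id, weeks = r$week,
                  sentinel_epsilon = sentinel_epsilon)
  })
  chain_panel(series)
}

#' Flatten a panel back to long-format records
#'
#' Inverse of [build_panel()]: returns one row per pharmacy-week.
#'
#' @param panel A `chain_panel`.
#' @return A data.frame with columns `pharmacy_id`, `week`, `quantity`.
#' @export
flatten_panel <- function(panel) {
  stopifnot(inherits(panel, "chain_panel"))
  do.call(rbind, lapply(panel$pharmacies, function(s)
    data.frame(pharmacy_id = s$series_id, week = s$weeks,
               quantity = s$values, stringsAsFactors = FALSE)))
}

#' Aggregate a panel to the chain level
#'
#' Week-wise sum of all member pharmacies, the chain-level series
#' Y_t = sum_i Y_i(t) used by the aggregate planning approaches.
#'
#' Missingness in the aggregate is governed by `missing_rule`: with the
#' default `"all"`, a chain week is a shortage week only when every member
#' pharmacy was in shortage that week (a chain-wide stockout). With
#' `keep_sentinels = TRUE` the raw sums are kept as ordinary observations
#' (no week is masked), which reproduces published chain tables where
#' stockout sentinels flow straight into the aggregate.
#'
#' @param panel A `chain_panel`.
#' @param keep_sentinels If `TRUE`, clear the missing mask and keep raw
#'   sentinel sums as data. Default `FALSE`.
#' @param missing_rule Either `"all"` (aggregate week missing iff all
#'   members missing, the default) or `"any"`.
#' @return A `weekly_series` with `series_id = "chain"`.
#' @examples
#' p <- build_panel(data.frame(pharmacy_id = rep(c("a", "b"), each = 3),
#'                             week = rep(1:3, 2),
#'                             quantity = c(1, 2, 3, 10, 20, 30)))
#' aggregate_chain(p)$values # 11 22 33
#' @export
aggregate_chain <- function(panel, keep_sentinels = FALSE,
                            missing_rule = c("all", "any")) {
  stopifnot(inherits(panel, "chain_panel"))
  missing_rule <- match.arg(missing_rule)
  vals <- rowSums(vapply(panel$pharmacies, function(s) s$values,
                         numeric(length(panel$weeks))))
  mm <- vapply(panel$pharmacies, function(s) s$missing_mask,
               logical(length(panel$weeks)))
  mm <- if (is.matrix(mm)) mm else matrix(mm, ncol = panel$n)
  miss <- if (missing_rule == "all") apply(mm, 1L, all) else apply(mm, 1L, any)
  if (keep_sentinels) miss <- rep(FALSE, length(vals))
  weekly_series(vals, series_id = "chain", weeks = panel$weeks,
                missing = miss)
}
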