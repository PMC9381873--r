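#' Read a long-format weekly sales CSV
#'
#' Expects a UTF-8 CSV with header `pharmacy_id,week,quantity`. Decimal
#' commas in the quantity column (e.g. a sentinel printed as "0,0001") are
#' normalized to decimal points on read.
#'
#' @param path Input CSV path.
#' @param sentinel_epsilon Shortage sentinel threshold, see
#'   [weekly_series()].
#' @return A [chain_panel()].
#' @export
read_sales_csv <- function(path, sentinel_epsilon = 0.001) {
  if (!file.exists(path)) stop("read_sales_csv: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("pharmacy_id", "week", "quantity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_sales_csv: ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (is.character(df$quantity)) {
    q <- suppressWarnings(as.numeric(gsub(",", ".", df$quantity,
                                          fixed = TRUE)))
    bad <- which(is.na(q) & !is.na(df$quantity))
    if (length(bad))
      stop("read_sales_csv: unparseable quantity at data line ", bad[1L],
           ": '", df$quantity[bad[1L]], "'")
    df$quantity <- q
  }
  build_panel(df, sentinel_epsilon = sentinel_epsilon)
}

#' Write a panel as a long-format sales CSV
#'
#' @param panel A [chain_panel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sales_csv <- function(panel, path) {
  utils::write.csv(flatten_panel(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Simulate a chain panel and write it to CSV
#'
#' Runs the synthetic generator and writes the long-format CSV. The same
#' seed and specs produce a byte-identical file.
#'
#' @param path Output CSV path.
#' @param specs List of [pharmacy_spec()]. Default:
#'   [default_chain_specs()].
#' @param seed Integer seed.
#' @return The generated [chain_panel()], invisibly.
#' @export
simulate_sales_csv <- function(path, specs = default_chain_specs(),
                               seed = 1L) {
  panel <- generate_chain(specs, seed = seed)
  write_sales_csv(panel, path)
  invisible(panel)
}

#' Run a planning approach on a sales CSV and write report files
#'
#' End-to-end file interface: reads the long-format sales CSV, runs the
#' requested planning approach, and writes into `output_dir`:
#' \itemize{
#'   \item `forecasts.csv` -- week, actual and one fitted-forecast column
#'     per method;
#'   \item `accuracy.csv` -- MAPE, MSE, U2 and evaluated-week count per
#'     method (full precision);
#'   \item `cleaning.csv` -- the imputation/winsorization audit trail;
#'   \item `selection.txt` -- the selected best method and its next-week
#'     chain forecast.
#' }
#'
#' @param input_csv Input sales CSV.
#' @param output_dir Output directory (created if absent).
#' @param approach Planning approach 1-4. Default 1.
#' @param ... Passed to [run_approach()].
#' @return The `approach_result`, invisibly.
#' @export
forecast_sales_csv <- function(input_csv, output_dir, approach = 1L, ...) {
  panel <- read_sales_csv(input_csv)
  res <- run_approach(panel, approach = approach, ...)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  fc <- data.frame(week = panel$weeks, actual = res$actuals)
  for (m in names(res$forecasts)) fc[[m]] <- res$forecasts[[m]]$fitted
  utils::write.csv(fc, file.path(output_dir, "forecasts.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(res$accuracy),
                   file.path(output_dir, "accuracy.csv"), row.names = FALSE)
  write_cleaning_report(res$cleaning, file.path(output_dir, "cleaning.csv"))
  writeLines(c(paste("approach:", res$approach),
               paste("best_method:", res$best_method),
               paste("next_week_forecast:",
                     format(res$chain_forecast$future[1L], digits = 10))),
             file.path(output_dir, "selection.txt"))
  invisible(res)
}
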