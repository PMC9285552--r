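#' Read a cow table
#'
#' One row per cow-period. Expected columns: cow_id, live_weight (kg),
#' milk_yield (kg/day), milk_fat (%), milk_protein (%), dmi (kg/day),
#' days_in_milk, gei (MJ/day), diet. Basic physiologic invariants are
#' checked on read.
#'
#' @param path CSV file with header, decimal point, UTF-8.
#' @return Data frame.
#' @export
read_cow_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow_id", "live_weight", "milk_yield", "milk_fat",
            "milk_protein", "dmi", "days_in_milk", "gei", "diet")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("cow table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (any(d$live_weight <= 0)) stop("live_weight must be positive")
  if (any(d$milk_yield < 0) || any(d$dmi < 0) || any(d$gei < 0) ||
      any(d$days_in_milk < 0)) {
    stop("milk_yield, dmi, gei and days_in_milk must be non-negative")
  }
  if (any(d$milk_fat < 0 | d$milk_fat > 100) ||
      any(d$milk_protein < 0 | d$milk_protein > 100)) {
    stop("milk_fat and milk_protein must be percentages in [0, 100]")
  }
  d
}

#' Read a 1-Hz gas-concentration trace
#'
#' Column dialect: \code{time_s}, \code{ch4_ppm}, \code{co2_ppm}, optional
#' \code{flow_lpm} (head-box traces). Percent columns (\code{ch4_pct},
#' \code{co2_pct}) are accepted and converted on read (1% = 10,000 ppm).
#' Timestamps must advance by exactly 1 s within the file.
#'
#' @param path CSV file.
#' @return Data frame with columns t, ch4, co2 and (if present) flow.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(d)) stop("trace lacks a time_s column")
  ch4 <- if ("ch4_ppm" %in% names(d)) d$ch4_ppm
         else if ("ch4_pct" %in% names(d)) d$ch4_pct * 1e4
         else stop("trace lacks ch4_ppm/ch4_pct")
  co2 <- if ("co2_ppm" %in% names(d)) d$co2_ppm
         else if ("co2_pct" %in% names(d)) d$co2_pct * 1e4
         else stop("trace lacks co2_ppm/co2_pct")
  if (nrow(d) > 1 && any(diff(d$time_s) != 1)) {
    stop("trace timestamps must be gap-free at 1 Hz")
  }
  if (any(ch4 < 0) || any(co2 < 0)) stop("concentrations must be >= 0")
  out <- data.frame(t = d$time_s, ch4 = ch4, co2 = co2)
  if ("flow_lpm" %in% names(d)) {
    if (any(d$flow_lpm <= 0)) stop("flow must be positive")
    out$flow <- d$flow_lpm
  }
  out
}

#' Write a gas trace in the package CSV dialect
#'
#' @param trace Data frame with t, ch4, co2 and optionally flow.
#' @param path Output CSV.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(time_s = trace$t, ch4_ppm = trace$ch4,
                    co2_ppm = trace$co2)
  if (!is.null(trace$flow)) out$flow_lpm <- trace$flow
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a 10-min activity log
#'
#' @param path CSV with columns bin_start (ISO-8601 timestamp or numeric
#'   seconds) and activity.
#' @return Data frame with bin_start (numeric seconds or POSIXct) and
#'   activity; bins are checked sorted and non-overlapping.
#' @export
read_activity_csv <- function(path, bin_s = 600) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("bin_start", "activity") %in% names(d))) {
    stop("activity log needs bin_start and activity columns")
  }
  if (!is.numeric(d$bin_start)) {
    d$bin_start <- as.POSIXct(d$bin_start, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                             "%Y-%m-%d %H:%M:%S"))
  }
  s <- as.numeric(d$bin_start)
  if (is.unsorted(s)) stop("activity bins must be sorted")
  if (nrow(d) > 1 && any(diff(s) < bin_s)) {
    stop("activity bins overlap")
  }
  ok <- c("eating", "ruminating", "moving", "standing", "lying")
  if (any(!d$activity %in% ok)) {
    stop("unknown activity label(s): ",
         paste(unique(setdiff(d$activity, ok)), collapse = ", "))
  }
  d
}
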