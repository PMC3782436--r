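#' Daily rainfall series
#'
#' Validated container for a gap-free daily rainfall record: a contiguous
#' calendar-date grid and nonnegative rainfall in mm/day.
#'
#' @param dates `Date` vector, one entry per day, contiguous and increasing.
#' @param rainfall numeric, mm/day, all nonnegative.
#' @return A data frame of class `daily_series` with columns `date`,
#'   `rain_mm`.
#' @export
daily_series <- function(dates, rainfall) {
  dates <- as.Date(dates)
  rainfall <- as.numeric(rainfall)
  if (length(dates) == 0) stop("empty series")
  if (length(dates) != length(rainfall)) stop("dates/rainfall length mismatch")
  if (anyNA(dates) || anyNA(rainfall)) stop("missing values are not allowed")
  if (length(dates) > 1 && any(diff(dates) != 1)) {
    stop("date grid has gaps or is unordered")
  }
  if (any(rainfall < 0)) stop("negative rainfall")
  structure(data.frame(date = dates, rain_mm = rainfall),
            class = c("daily_series", "data.frame"))
}

#' Read a daily rainfall CSV
#'
#' Expects a header `date,rain_mm` with ISO-8601 dates.
#'
#' @param path file path.
#' @return A [daily_series()].
#' @export
read_daily_rainfall <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "rain_mm") %in% names(d))) {
    stop("expected columns 'date' and 'rain_mm'")
  }
  daily_series(as.Date(d$date), d$rain_mm)
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("Daily rainfall series: %d days, %s to %s, mean %.2f mm/day\n",
              nrow(x), min(x$date), max(x$date), mean(x$rain_mm)))
  invisible(x)
}
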