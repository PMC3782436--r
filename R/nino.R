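#' Read a monthly Nino 3.4 index table
#'
#' Accepts either the NOAA CPC wide layout (a year column followed by twelve
#' monthly columns) or a long CSV `year,month,value`.  The wide layout is
#' melted to long on read.
#'
#' @param path file path.
#' @return Data frame of class `monthly_index` with columns `year`, `month`,
#'   `value`, sorted and checked for duplicate (year, month) keys.
#' @export
read_nino34 <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- tolower(names(d))
  if (all(c("year", "month", "value") %in% nm)) {
    names(d) <- nm
    out <- d[c("year", "month", "value")]
  } else if (ncol(d) == 13) {
    names(d)[1] <- "year"
    out <- data.frame(
      year = rep(d$year, each = 12),
      month = rep(1:12, times = nrow(d)),
      value = as.numeric(t(as.matrix(d[, 2:13]))))
  } else {
    stop("unrecognized index layout: need year,month,value or year + 12 columns")
  }
  monthly_index(out$year, out$month, out$value)
}

#' Monthly climate-index series
#'
#' @param year,month,value integer years, months 1-12 and index values
#'   (sea-surface-temperature anomalies, degrees C, for Nino 3.4).
#' @return Data frame of class `monthly_index`.
#' @export
monthly_index <- function(year, month, value) {
  stopifnot(all(month %in% 1:12), length(year) == length(month),
            length(month) == length(value))
  out <- data.frame(year = as.integer(year), month = as.integer(month),
                    value = as.numeric(value))
  if (anyDuplicated(out[c("year", "month")])) {
    stop("duplicate (year, month) keys")
  }
  out <- out[order(out$year, out$month), ]
  row.names(out) <- NULL
  class(out) <- c("monthly_index", "data.frame")
  out
}

#' Season-weighted mean of a monthly index
#'
#' Mean of the monthly values over an arbitrary season span with incomplete
#' months proportionately weighted: each month's weight is the number of
#' season days (inclusive endpoints) falling inside it, so the weights sum
#' to the season duration.
#'
#' @param index a [monthly_index()].
#' @param onset,cessation season endpoints (inclusive).
#' @return Weighted mean index value.
#' @examples
#' idx <- monthly_index(rep(2000, 2), 1:2, c(1.0, -0.5))
#' # Jan 16 - Feb 28: (16 * 1.0 + 28 * -0.5) / 44
#' seasonal_nino(idx, as.Date("2000-01-16"), as.Date("2000-02-28"))
#' @export
seasonal_nino <- function(index, onset, cessation) {
  onset <- as.Date(onset); cessation <- as.Date(cessation)
  if (cessation < onset) stop("empty span")
  days <- seq(onset, cessation, by = "day")
  key <- format(days, "%Y-%m")
  w <- table(key)
  ym <- do.call(rbind, strsplit(names(w), "-"))
  vals <- vapply(seq_len(nrow(ym)), function(i) {
    v <- index$value[index$year == as.integer(ym[i, 1]) &
                     index$month == as.integer(ym[i, 2])]
    if (length(v) != 1) {
      stop("index is missing ", ym[i, 1], "-", ym[i, 2])
    }
    v
  }, numeric(1))
  sum(vals * as.integer(w)) / sum(w)
}

#' Attach season-weighted Nino 3.4 values to a descriptor table
#'
#' Adds a `nino34` column: for every season row, the [seasonal_nino()] mean
#' over that row's own onset-cessation span.
#'
#' @param table a [build_descriptor_table()] result.
#' @param index a [monthly_index()].
#' @return The table with a `nino34` column.
#' @export
add_seasonal_nino <- function(table, index) {
  table$nino34 <- vapply(seq_len(nrow(table)), function(i) {
    seasonal_nino(index, table$onset[i], table$cessation[i])
  }, numeric(1))
  table
}
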