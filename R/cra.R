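#' Cumulative rainfall anomaly
#'
#' Running sum of daily rainfall minus a constant daily reference rate.  The
#' CRA turns a spiky daily record into a waveform whose sustained rises mark
#' the wet season and sustained falls the dry season; its turning points are
#' the season boundaries.  With the reference equal to the record's own mean
#' the series telescopes to zero at the last day.
#'
#' @param series a [daily_series()].
#' @param reference `"long-term-mean"` (default: mean daily rainfall over
#'   the full record) or a strictly positive rate in mm/day.
#' @return A data frame of class `cra_series` with columns `date`, `cra`
#'   (mm) and attributes `reference` and `rain_mm`.
#' @examples
#' s <- daily_series(as.Date("2000-01-01") + 0:3, c(2, 0, 0, 2))
#' compute_cra(s)$cra  # 1, 0, -1, 0
#' @export
compute_cra <- function(series, reference = "long-term-mean") {
  stopifnot(inherits(series, "daily_series"))
  if (identical(reference, "long-term-mean")) {
    ref <- mean(series$rain_mm)
  } else {
    ref <- as.numeric(reference)
    if (!is.finite(ref) || ref <= 0) stop("reference rate must be positive")
  }
  out <- data.frame(date = series$date,
                    cra = cumsum(series$rain_mm - ref))
  attr(out, "reference") <- ref
  attr(out, "rain_mm") <- series$rain_mm
  class(out) <- c("cra_series", "data.frame")
  out
}

#' Inclusive day count between two dates
#'
#' Both endpoint days are counted, the convention under which a May 21 to
#' October 1 wet season lasts 134 days and the complementary October 2 to
#' May 20 dry season (crossing New Year) lasts 231 days.
#'
#' @param onset,cessation `Date`s (or coercible); `cessation` must not
#'   precede `onset`.
#' @return Integer number of days.
#' @examples
#' inclusive_duration(as.Date("2001-05-21"), as.Date("2001-10-01"))  # 134
#' inclusive_duration(as.Date("2001-10-02"), as.Date("2002-05-20"))  # 231
#' @export
inclusive_duration <- function(onset, cessation) {
  onset <- as.Date(onset); cessation <- as.Date(cessation)
  d <- as.integer(cessation - onset) + 1L
  if (any(d < 1L)) stop("cessation precedes onset")
  d
}

#' Seasonal rainfall total
#'
#' Sum of daily rainfall over the inclusive span, in cm.
#'
#' @param series a [daily_series()].
#' @param onset,cessation span endpoints (inclusive), inside the record.
#' @return Rainfall in cm.
#' @export
season_rainfall <- function(series, onset, cessation) {
  onset <- as.Date(onset); cessation <- as.Date(cessation)
  if (onset < min(series$date) || cessation > max(series$date)) {
    stop("span outside the record")
  }
  sel <- series$date >= onset & series$date <= cessation
  sum(series$rain_mm[sel]) / 10
}

#' Trend consistency of a season
#'
#' Coefficient of determination (R-squared) of an ordinary least-squares
#' line of the CRA against day index within the season.  Values near 1 mean
#' an uninterrupted drying (dry season) or moistening (wet season) trend;
#' storms or droughts that punctuate the trend pull it down.
#'
#' @param cra a [compute_cra()] result.
#' @param onset,cessation season endpoints (inclusive), at least 3 days.
#' @return R-squared in `[0, 1]`, or `NA` with a warning for a
#'   zero-variance CRA segment.
#' @export
trend_consistency <- function(cra, onset, cessation) {
  onset <- as.Date(onset); cessation <- as.Date(cessation)
  sel <- cra$date >= onset & cra$date <= cessation
  y <- cra$cra[sel]
  if (length(y) < 3) stop("season span must cover at least 3 days")
  if (stats::var(y) < .Machine$double.eps) {
    warning("zero-variance CRA segment; trend consistency undefined")
    return(NA_real_)
  }
  x <- seq_along(y)
  stats::cor(x, y)^2
}

#' Detect wet-season boundaries from a CRA waveform
#'
#' Within each calendar year the wet-season onset is taken as the day after
#' the CRA minimum inside the onset search window (the turning point where
#' the waveform stops falling and begins its sustained rise) and the
#' cessation as the day of the CRA maximum inside the cessation window.
#' Years whose windowed segment is flat (no turning point, e.g. constant
#' rainfall) are flagged rather than dropped silently.
#'
#' @param cra a [compute_cra()] result.
#' @param years integer years to scan; default all years fully covered.
#' @param onset_window,cessation_window two-element character vectors
#'   `c("mm-dd", "mm-dd")` delimiting the search windows; defaults
#'   Mar 1 - Jul 31 and Aug 1 - Dec 31.
#' @return Data frame with columns `year`, `wet_onset`, `wet_cessation`
#'   (`Date`, `NA` when flagged) and `detected` (logical).
#' @export
detect_seasons <- function(cra, years = NULL,
                           onset_window = c("03-01", "07-31"),
                           cessation_window = c("08-01", "12-31")) {
  stopifnot(inherits(cra, "cra_series"))
  yr <- as.integer(format(cra$date, "%Y"))
  if (is.null(years)) {
    full <- table(yr)
    years <- as.integer(names(full))[full >= 365]
  }
  res <- lapply(years, function(y) {
    ow <- as.Date(paste0(y, "-", onset_window))
    cw <- as.Date(paste0(y, "-", cessation_window))
    if (ow[1] < min(cra$date) || cw[2] > max(cra$date)) {
      stop("search window outside the record for year ", y)
    }
    osel <- which(cra$date >= ow[1] & cra$date <= ow[2])
    csel <- which(cra$date >= cw[1] & cra$date <= cw[2])
    oseg <- cra$cra[osel]
    cseg <- cra$cra[csel]
    flat <- diff(range(oseg)) < 1e-9 || diff(range(cseg)) < 1e-9
    if (flat) {
      return(data.frame(year = y, wet_onset = as.Date(NA),
                        wet_cessation = as.Date(NA), detected = FALSE))
    }
    onset <- cra$date[osel[which.min(oseg)]] + 1L
    cess <- cra$date[csel[which.max(cseg)]]
    ok <- cess > onset
    data.frame(year = y,
               wet_onset = if (ok) onset else as.Date(NA),
               wet_cessation = if (ok) cess else as.Date(NA),
               detected = ok)
  })
  do.call(rbind, res)
}

#' Build the per-year season descriptor table
#'
#' Runs the CRA season detection over a daily record and assembles one wet
#' and one dry row per season-year: onset, cessation, inclusive duration,
#' seasonal rainfall (cm) and trend consistency.  The dry season runs from
#' the day after the wet cessation to the day before the next year's wet
#' onset (it spans New Year) and is labelled by the calendar year of its
#' onset.  Years whose boundaries could not be detected are flagged and
#' excluded, with a message giving the count.
#'
#' @param series a [daily_series()].
#' @param years integer years to characterize; default all years fully
#'   covered with the margins the dry season needs.
#' @param reference passed to [compute_cra()].
#' @param onset_window,cessation_window passed to [detect_seasons()].
#' @return Data frame with columns `year`, `season` (`"wet"`/`"dry"`),
#'   `onset`, `cessation`, `onset_doy`, `cessation_doy`, `duration_days`,
#'   `rainfall_cm`, `trend_r2`.
#' @export
build_descriptor_table <- function(series, years = NULL,
                                   reference = "long-term-mean",
                                   onset_window = c("03-01", "07-31"),
                                   cessation_window = c("08-01", "12-31")) {
  cra <- compute_cra(series, reference)
  bounds <- detect_seasons(cra, years = years,
                           onset_window = onset_window,
                           cessation_window = cessation_window)
  n_flag <- sum(!bounds$detected)
  if (n_flag > 0) {
    message(n_flag, " year(s) flagged with no detectable season; excluded")
  }
  bounds <- bounds[bounds$detected, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(bounds))) {
    y <- bounds$year[i]
    w_on <- bounds$wet_onset[i]
    w_off <- bounds$wet_cessation[i]
    rows[[length(rows) + 1]] <- data.frame(
      year = y, season = "wet", onset = w_on, cessation = w_off,
      onset_doy = as.integer(format(w_on, "%j")),
      cessation_doy = as.integer(format(w_off, "%j")),
      duration_days = inclusive_duration(w_on, w_off),
      rainfall_cm = season_rainfall(series, w_on, w_off),
      trend_r2 = trend_consistency(cra, w_on, w_off))
    nxt <- bounds[bounds$year == y + 1, , drop = FALSE]
    if (nrow(nxt) == 1) {
      d_on <- w_off + 1L
      d_off <- nxt$wet_onset[1] - 1L
      if (d_off >= d_on + 2) {
        rows[[length(rows) + 1]] <- data.frame(
          year = y, season = "dry", onset = d_on, cessation = d_off,
          onset_doy = as.integer(format(d_on, "%j")),
          cessation_doy = as.integer(format(d_off, "%j")),
          duration_days = inclusive_duration(d_on, d_off),
          rainfall_cm = season_rainfall(series, d_on, d_off),
          trend_r2 = trend_consistency(cra, d_on, d_off))
      }
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Write a descriptor table as TSV
#'
#' @param table a [build_descriptor_table()] result (possibly with a
#'   `nino34` column from [add_seasonal_nino()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
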