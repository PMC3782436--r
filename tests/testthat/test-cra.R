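test_that("CRA is the running sum of anomalies and telescopes to zero", {
  s <- daily_series(as.Date("2000-01-01") + 0:3, c(2, 0, 0, 2))
  cra <- compute_cra(s)  # reference = mean = 1 mm/day
  expect_equal(cra$cra, c(1, 0, -1, 0))

  # constant rainfall equal to the reference: identically zero
  s2 <- daily_series(as.Date("2000-01-01") + 0:99, rep(3, 100))
  expect_equal(compute_cra(s2, reference = 3)$cra, rep(0, 100))

  # telescoping and exact recurrence on a random series
  set.seed(11)
  rain <- rgamma(400, 1.2, 0.3)
  s3 <- daily_series(as.Date("2005-01-01") + 0:399, rain)
  cra3 <- compute_cra(s3)
  expect_equal(cra3$cra[400], 0, tolerance = 1e-9)
  expect_equal(diff(cra3$cra), (rain - mean(rain))[-1], tolerance = 1e-12)
})

test_that("series validation rejects bad inputs", {
  expect_error(daily_series(as.Date(character()), numeric()), "empty")
  expect_error(daily_series(as.Date("2000-01-01") + c(0, 2), c(1, 1)),
               "gaps")
  expect_error(daily_series(as.Date("2000-01-01") + 0:1, c(1, -1)),
               "negative")
  s <- daily_series(as.Date("2000-01-01") + 0:1, c(1, 1))
  expect_error(compute_cra(s, reference = 0), "positive")
})

test_that("inclusive duration matches the published season-length anchors", {
  expect_identical(inclusive_duration(as.Date("2001-05-21"),
                                      as.Date("2001-10-01")), 134L)
  expect_identical(inclusive_duration(as.Date("2001-10-02"),
                                      as.Date("2002-05-20")), 231L)
  expect_identical(inclusive_duration(as.Date("2001-03-03"),
                                      as.Date("2001-03-03")), 1L)
  expect_error(inclusive_duration(as.Date("2001-03-04"),
                                  as.Date("2001-03-03")), "precedes")
})

test_that("season rainfall sums daily mm into cm and is additive", {
  s <- daily_series(as.Date("2001-01-01") + 0:29,
                    c(rep(10, 10), rep(0, 20)))
  expect_equal(season_rainfall(s, "2001-01-01", "2001-01-10"), 10)
  expect_equal(season_rainfall(s, "2001-01-11", "2001-01-30"), 0)
  set.seed(4)
  rain <- round(rgamma(365, 0.8, 0.2), 2)
  s2 <- daily_series(as.Date("2001-01-01") + 0:364, rain)
  on <- as.Date("2001-04-07"); off <- as.Date("2001-09-20")
  expect_equal(season_rainfall(s2, on, off),
               sum(rain[as.Date("2001-01-01") + 0:364 >= on &
                        as.Date("2001-01-01") + 0:364 <= off]) / 10)
  # additivity over a partition of the record
  expect_equal(season_rainfall(s2, "2001-01-01", off - 1) +
                 season_rainfall(s2, off, "2001-12-31"),
               sum(rain) / 10)
  expect_error(season_rainfall(s2, "2000-12-01", off), "outside")
})

test_that("trend consistency is the R2 of a line through the CRA segment", {
  # strictly linear CRA: constant rainfall above the reference
  s <- daily_series(as.Date("2001-01-01") + 0:59, rep(5, 60))
  cra <- compute_cra(s, reference = 2)
  expect_equal(trend_consistency(cra, "2001-01-05", "2001-02-05"), 1)

  # symmetric tent: rise then mirrored fall, linear term explains nothing
  tent <- daily_series(as.Date("2001-01-01") + 0:39,
                       c(rep(4, 20), rep(0, 20)))
  cra_t <- compute_cra(tent, reference = 2)
  expect_lt(trend_consistency(cra_t, "2001-01-01", "2001-02-09"), 0.05)

  # line plus centered noise: strictly between 0 and 1, equals direct OLS
  set.seed(9)
  rain <- pmax(0, 3 + rnorm(50))
  sn <- daily_series(as.Date("2001-03-01") + 0:49, rain)
  cra_n <- compute_cra(sn, reference = 1)
  r2 <- trend_consistency(cra_n, "2001-03-01", "2001-04-19")
  expect_gt(r2, 0); expect_lt(r2, 1)
  expect_equal(r2, summary(lm(cra_n$cra ~ seq_len(50)))$r.squared)

  expect_error(trend_consistency(cra_n, "2001-03-01", "2001-03-02"),
               "3 days")
  flat <- compute_cra(daily_series(as.Date("2001-01-01") + 0:9,
                                   rep(2, 10)), reference = 2)
  expect_warning(r <- trend_consistency(flat, "2001-01-02", "2001-01-08"),
                 "zero-variance")
  expect_true(is.na(r))
})

test_that("season boundaries sit at the CRA turning points", {
  # 100 dry days, 100 wet days at 10 mm, 100 dry days
  rain <- c(rep(0, 100), rep(10, 100), rep(0, 100))
  s <- daily_series(as.Date("2001-01-01") + 0:299, rain)
  cra <- compute_cra(s)
  b <- detect_seasons(cra, years = 2001,
                      onset_window = c("01-02", "06-01"),
                      cessation_window = c("06-02", "10-20"))
  expect_true(b$detected)
  expect_equal(as.integer(format(b$wet_onset, "%j")), 101L)
  expect_equal(as.integer(format(b$wet_cessation, "%j")), 200L)

  # constant rainfall: flat CRA, flagged not crashed
  flat <- compute_cra(daily_series(as.Date("2001-01-01") + 0:299,
                                   rep(2, 300)))
  bf <- detect_seasons(flat, years = 2001,
                       onset_window = c("01-02", "06-01"),
                       cessation_window = c("06-02", "10-20"))
  expect_false(bf$detected)
  expect_true(is.na(bf$wet_onset))

  expect_error(detect_seasons(cra, years = 2002), "outside")
})

test_that("descriptor table partitions the year and is shift-invariant", {
  clim <- generate_daily_climate(climate_config(years = 6,
                                                start_year = 1980,
                                                seed = 21))
  desc <- build_descriptor_table(clim$series, years = 1980:1986)
  wet <- desc[desc$season == "wet", ]
  dry <- desc[desc$season == "dry", ]
  expect_true(all(1980:1986 %in% wet$year))
  # wet + dry duration of a season-year spans onset to next onset
  for (y in 1980:1985) {
    w <- wet[wet$year == y, ]; d <- dry[dry$year == y, ]
    nxt <- wet[wet$year == y + 1, ]
    expect_equal(w$duration_days + d$duration_days,
                 as.integer(nxt$onset - w$onset))
  }
  # boundaries partition: wet cessation + 1 = dry onset
  expect_equal(dry$onset, wet$cessation[match(dry$year, wet$year)] + 1L)
  expect_true(all(desc$trend_r2 >= 0 & desc$trend_r2 <= 1))

  # translating all dates by exactly 28 years (preserving leap structure)
  s <- clim$series
  shifted <- daily_series(s$date + round(28 * 365.25), s$rain_mm)
  desc2 <- build_descriptor_table(shifted, years = 2008:2014)
  expect_equal(desc2$onset_doy, desc$onset_doy)
  expect_equal(desc2$duration_days, desc$duration_days)
  expect_equal(desc2$rainfall_cm, desc$rainfall_cm)
  expect_equal(desc2$trend_r2, desc$trend_r2)
})

test_that("a single season-year record with margins yields one wet row", {
  clim <- generate_daily_climate(climate_config(years = 1,
                                                start_year = 1990,
                                                seed = 3))
  desc <- build_descriptor_table(clim$series, years = 1990:1991)
  expect_equal(sum(desc$season == "wet" & desc$year == 1990), 1L)
})

test_that("rainfall CSV round-trips through the reader", {
  s <- daily_series(as.Date("2001-01-01") + 0:9, c(0, 1:9))
  f <- tempfile(fileext = ".csv")
  write.csv(s, f, row.names = FALSE)
  s2 <- read_daily_rainfall(f)
  expect_equal(s2$rain_mm, s$rain_mm)
  expect_equal(s2$date, s$date)
})
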