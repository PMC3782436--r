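test_that("descriptor-level sampler hits the implied covariance", {
  gen <- model_catalog("fire_second_best")
  std <- standardized_sigma(gen)
  expect_equal(unname(diag(std$sigma)), rep(1, 5))
  expect_true(all(std$error_var > 0))
  d <- sample_from_path_model(gen, 1e6, seed = 8)
  expect_lt(max(abs(cov(d)[rownames(std$sigma), colnames(std$sigma)] -
                      std$sigma)), 0.01)
  # reproducibility and seed isolation
  d1 <- sample_from_path_model(gen, 50, seed = 123)
  d2 <- sample_from_path_model(gen, 50, seed = 123)
  expect_identical(d1, d2)
  expect_error(sample_from_path_model(free_skeleton("dry_best"), 10),
               "free coefficients")
})

test_that("noise-free climate reproduces its own season calendar", {
  cfg <- climate_config(years = 4, start_year = 2000, boundary_sd = 0,
                        wet_p = 1, dry_p = 1, gamma_shape = 5000,
                        coupling = 0, seed = 2)
  clim <- generate_daily_climate(cfg)
  desc <- build_descriptor_table(clim$series, years = 2000:2004)
  wet <- desc[desc$season == "wet", ]
  i <- match(wet$year, clim$truth$year)
  expect_true(all(abs(as.integer(wet$onset - clim$truth$wet_onset[i]))
                  <= 2))
  expect_true(all(abs(as.integer(wet$cessation -
                                 clim$truth$wet_cessation[i])) <= 2))
})

test_that("default climate matches the site's seasonal rainfall anchors", {
  clim <- generate_daily_climate(climate_config(seed = 7))
  desc <- build_descriptor_table(clim$series, years = 1950:2008)
  desc <- desc[desc$year <= 2007, ]
  dry <- desc[desc$season == "dry", ]
  wet <- desc[desc$season == "wet", ]
  expect_gt(mean(dry$rainfall_cm), 42 - 10)
  expect_lt(mean(dry$rainfall_cm), 42 + 10)
  expect_gt(mean(wet$rainfall_cm), 89 - 15)
  expect_lt(mean(wet$rainfall_cm), 89 + 15)
  # boundary jitter of about a month propagates into the descriptors
  expect_gt(sd(wet$onset_doy), 15)
  # same seed, same record
  clim2 <- generate_daily_climate(climate_config(seed = 7))
  expect_identical(clim2$series$rain_mm, clim$series$rain_mm)
  expect_error(climate_config(enso_phi = 1.2), "enso_phi")
})

test_that("decoupled ENSO leaves dry-season rainfall uncorrelated", {
  rs <- sapply(1:12, function(s) {
    clim <- generate_daily_climate(
      climate_config(years = 15, start_year = 1990, coupling = 0,
                     seed = 100 + s))
    desc <- build_descriptor_table(clim$series, years = 1990:2005)
    dry <- desc[desc$season == "dry" & desc$year <= 2004, ]
    dry <- add_seasonal_nino(dry, clim$nino)
    cor(dry$nino34, dry$rainfall_cm)
  })
  # mean correlation across seeds consistent with zero
  expect_lt(abs(mean(rs)), 2.5 * sd(rs) / sqrt(length(rs)))
})

test_that("fire generator follows the configured path structure", {
  set.seed(33)
  n <- 400
  desc <- data.frame(year = seq_len(n) + 1950,
                     nino = rnorm(n, 0, 0.8),
                     rainfall = rnorm(n, 42, 10),
                     tc_wet = runif(n, 0.3, 0.98))
  fires <- generate_fire_records(desc, fire_config(seed = 5))
  expect_true(all(fires$n_fires >= 0))
  expect_true(all(fires$n_fires == round(fires$n_fires)))
  expect_true(all(fires$area_burned_ha >= 0))
  # configured negative tc_wet -> n_fires coupling shows up
  expect_lt(cor(reflect_ln(desc$tc_wet), sqrt(fires$n_fires)), -0.3)
  expect_lt(cor(desc$rainfall, sqrt(fires$area_burned_ha)), -0.2)
  # determinism
  fires2 <- generate_fire_records(desc, fire_config(seed = 5))
  expect_identical(fires, fires2)

  # all-zero coefficients: fires independent of climate
  cf0 <- fire_config(coefficients = c("n_fires->area" = 0), seed = 6)
  f0 <- generate_fire_records(desc, cf0)
  expect_lt(abs(cor(desc$rainfall, sqrt(f0$area_burned_ha))), 0.12)
  expect_lt(abs(cor(reflect_ln(desc$tc_wet), sqrt(f0$n_fires))), 0.12)

  # truncation at zero is reported
  cheap <- fire_config(area_mean = 2, area_sd = 20, seed = 7)
  expect_message(ft <- generate_fire_records(desc, cheap), "truncated")
  expect_gt(attr(ft, "truncated"), 0)
  expect_error(generate_fire_records(desc[-2], fire_config()), "missing")
})

test_that("fire records sampled from the model refit with the right signs", {
  gen <- model_catalog("fire_second_best")
  skel <- free_skeleton("fire_second_best")
  keys <- paste0(gen$edges$from, "->", gen$edges$to)
  hits <- sapply(1:40, function(r) {
    d <- sample_from_path_model(gen, 30, seed = 700 + r)
    f <- fit_ml(cov(d), skel, 30, n_starts = 1, se = FALSE)
    all(sign(f$std_coefficients[keys]) == sign(gen$edges$fixed))
  })
  expect_gt(mean(hits), 0.5)
})
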