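test_that("path model validation enforces the structural invariants", {
  ok <- path_model(data.frame(from = c("x", "z"), to = c("y", "y")))
  expect_s3_class(ok, "path_model")
  expect_setequal(ok$exogenous, c("x", "z"))
  expect_equal(ok$endogenous, "y")

  expect_error(path_model(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "cycle")
  expect_error(path_model(data.frame(from = c("a", "a"), to = c("b", "b"))),
               "duplicate")
  expect_error(path_model(data.frame(from = "a", to = "a")), "self-loops")
  expect_error(path_model(data.frame(from = "a", to = "b", fixed = Inf)),
               "finite")
  expect_error(path_model(data.frame(from = "a", to = "b"),
                          covariances = data.frame(a = "a", b = "b")),
               "exogenous")
})

test_that("free-parameter and df counting matches the published models", {
  counts <- list(dry_start = 6L, wet_start = 5L, fire_start = 4L,
                 seasonal_saturated = 0L, fire_saturated = 0L)
  for (nm in names(counts)) {
    expect_identical(model_df(model_catalog(nm)), counts[[nm]],
                     label = nm)
  }
  # fitted models, refitted with all edges free
  expect_identical(model_df(free_skeleton("dry_best")), 4L)
  expect_identical(model_df(free_skeleton("wet_best")), 4L)
  expect_identical(model_df(free_skeleton("fire_second_best")), 5L)
  expect_identical(model_df(free_skeleton("fire_best")), 3L)
})

test_that("model spec files round-trip through the parser", {
  m <- model_catalog("fire_saturated")
  f <- tempfile(fileext = ".mod")
  write_path_model(m, f)
  m2 <- read_path_model(f)
  expect_equal(m2$variables, m$variables)
  expect_equal(m2$edges[c("from", "to", "fixed")],
               m$edges[c("from", "to", "fixed")])
  expect_equal(m2$covariances[c("a", "b")], m$covariances[c("a", "b")])

  bad <- tempfile()
  writeLines("x => y", bad)
  expect_error(read_path_model(bad), "bad edge line")
})

test_that("every catalog entry is a valid model with labelled provenance", {
  for (nm in model_catalog()) {
    m <- model_catalog(nm)
    expect_s3_class(m, "path_model")  # constructor enforces acyclicity
    expect_true(attr(m, "role") %in%
                  c("starting", "saturated-framework", "fitted-best"))
    if (attr(m, "role") == "fitted-best") {
      expect_false(anyNA(m$edges$fixed), label = nm)
      expect_true(all(m$edges$source %in%
                        c("reported", "carried", "synthetic")), label = nm)
    }
  }
  expect_error(model_catalog("no_such_model"), "unknown")
  # the printed dry-season starting structure: ENSO and onset exogenous,
  # four theory arrows
  dry <- model_catalog("dry_start")
  expect_setequal(dry$exogenous, c("nino", "onset"))
  expect_equal(nrow(dry$edges), 4L)
})

test_that("DOT export carries labels and significance line weights", {
  fit <- fit_sem(sample_from_path_model(model_catalog("dry_best"), 300,
                                        seed = 6),
                 free_skeleton("dry_best"))
  dot <- sem_dot(fit)
  expect_true(any(grepl("digraph", dot)))
  expect_true(any(grepl("penwidth", dot)))
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), nrow(fit$model$edges))
})
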