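test_that("implied covariance follows the structural algebra", {
  # no edges, unit variances: identity
  m0 <- path_model(data.frame(from = character(), to = character()),
                   variables = c("a", "b"))
  th0 <- c("var(a)" = 1, "var(b)" = 1)
  expect_equal(unname(implied_covariance(m0, th0)), diag(2))

  # single edge: Var(y) = b^2 Var(x) + e, Cov = b Var(x)
  m1 <- path_model(data.frame(from = "x", to = "y"))
  S1 <- implied_covariance(m1, c("x->y" = 0.7, "var(x)" = 1,
                                 "var(y)" = 0.4))
  expect_equal(S1["y", "y"], 0.7^2 + 0.4)
  expect_equal(S1["x", "y"], 0.7)

  # random acyclic model: matches Monte-Carlo covariance of 1e6 draws
  set.seed(31)
  gen <- random_dag_model(4)$generating
  d <- sample_from_path_model(gen, 1e6, seed = 14)
  target <- standardized_sigma(gen)$sigma
  expect_lt(max(abs(cov(d)[rownames(target), colnames(target)] - target)),
            0.01)
})

test_that("saturated fits are exact and simple regression is closed form", {
  set.seed(12)
  d <- data.frame(x = rnorm(80))
  d$y <- 0.6 * d$x + rnorm(80)
  S <- cov(d)
  m <- path_model(data.frame(from = "x", to = "y"))
  fit <- fit_ml(S, m, nrow(d))
  expect_equal(fit$df, 0L)
  expect_lt(fit$chisq, 1e-6)
  expect_true(is.na(fit$p_value))
  expect_true(fit$converged)
  # ML path estimate = S_xy / S_xx; standardized = sample correlation
  expect_equal(unname(fit$estimates["x->y"]), S["x", "y"] / S["x", "x"],
               tolerance = 1e-7)
  expect_equal(unname(fit$std_coefficients["x->y"]), cor(d$x, d$y),
               tolerance = 1e-7)
  expect_equal(unname(fit$r2["y"]), cor(d$x, d$y)^2, tolerance = 1e-7)
  # rescaling an observed variable leaves standardized coefficients alone
  d2 <- transform(d, x = x * 37)
  fit2 <- fit_sem(d2, m)
  expect_equal(fit2$std_coefficients, fit$std_coefficients,
               tolerance = 1e-6)
})

test_that("free coefficients are recovered from large samples", {
  gen <- model_catalog("dry_best")
  d <- sample_from_path_model(gen, 10000, seed = 99)
  fit <- fit_sem(d, free_skeleton("dry_best"))
  keys <- paste0(gen$edges$from, "->", gen$edges$to)
  est <- fit$std_coefficients[keys]
  # within 3 standard errors of the generating standardized values
  se <- fit$coef_table$se[match(keys, paste0(fit$coef_table$from, "->",
                                             fit$coef_table$to))]
  expect_true(all(abs(est - gen$edges$fixed) < 3 * se + 0.01))
  expect_false(fit$heywood)
})

test_that("fit_ml agrees with the closed-form recursive ML oracle", {
  set.seed(42)
  worst <- 0
  for (rep in 1:8) {
    p <- sample(3:5, 1)
    mod <- random_dag_model(p)
    d <- sample_from_path_model(mod$generating, 400)
    S <- cov(d)
    fit <- fit_ml(S, mod$free, 400)
    ora <- oracle_fit_recursive(S, mod$free, 400)
    expect_equal(fit$chisq, ora$chisq, tolerance = 1e-3)
    expect_lt(max(abs(fit$estimates[names(ora$theta)] - ora$theta)), 1e-3)
    expect_lt(max(abs(fit$std_coefficients - ora$std)), 1e-3)
    worst <- max(worst, abs(fit$chisq - ora$chisq))
  }
  expect_lt(worst, 1e-3)
})

test_that("adding a free edge never increases the chi-square", {
  set.seed(17)
  for (rep in 1:5) {
    gen <- random_dag_model(4, prob = 0.7)
    d <- sample_from_path_model(gen$generating, 120)
    S <- cov(d)
    full <- gen$free
    drop1 <- path_model(full$edges[-1, , drop = FALSE],
                        variables = full$variables)
    f_full <- fit_ml(S, full, 120, se = FALSE)
    f_drop <- fit_ml(S, drop1, 120, se = FALSE)
    expect_lte(f_full$chisq, f_drop$chisq + 1e-6)
  }
})

test_that("chi-square p-values and information criteria follow the forms", {
  expect_equal(round(chisq_pvalue(2.0, 3), 2), 0.57)
  expect_equal(round(chisq_pvalue(18.2, 5), 3), 0.003)
  expect_equal(chisq_pvalue(0, 4), 1)
  expect_true(is.na(chisq_pvalue(3, 0)))

  # zero free parameters: BCC equals the chi-square
  expect_equal(bcc(7.3, 0, 58, 5), 7.3)
  # worked value: chisq 10, q 5, n 58, p 5 -> 10 + 10 * 57 / 51
  expect_equal(bcc(10, 5, 58, 5), 10 + 10 * 57 / 51)
  # per-parameter penalty exceeds the AIC's 2 for all n > p + 2
  for (n in c(10, 30, 58, 1000)) {
    expect_gt(2 * (n - 1) / (n - 5 - 2), 2)
    expect_gt(bcc(5, 4, n, 5) - bcc(5, 2, n, 5), 4)  # AIC gap would be 4
  }
  expect_error(bcc(1, 1, 7, 5), "n > p")
})

test_that("standardization is exact on pre-standardized data", {
  gen <- model_catalog("wet_best")
  d <- sample_from_path_model(gen, 5000, seed = 55)
  d[] <- scale(d)  # unit variances: standardized = raw
  fit <- fit_sem(d, free_skeleton("wet_best"))
  keys <- paste0(gen$edges$from, "->", gen$edges$to)
  raw <- fit$coef_table$estimate[match(keys, paste0(fit$coef_table$from,
                                                    "->", fit$coef_table$to))]
  expect_equal(unname(fit$std_coefficients[keys]), raw, tolerance = 0.02)
})

test_that("R2 handles boundary structures", {
  set.seed(23)
  d <- data.frame(x = rnorm(60))
  d$y <- 2 * d$x + rnorm(60, sd = 1e-4)  # nearly deterministic
  fit <- fit_sem(d, path_model(data.frame(from = "x", to = "y")))
  expect_gt(r2_endogenous(fit, "y"), 0.999)
  expect_equal(r2_endogenous(fit, "x"), 0)  # no incoming edges
  expect_error(r2_endogenous(fit, "zz"), "not a model variable")
})

test_that("degenerate inputs are refused loudly", {
  m <- path_model(data.frame(from = "x", to = "y"))
  S_bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("x", "y"),
                                                    c("x", "y")))
  expect_error(fit_ml(S_bad, m, 50), "positive definite")
  S_ok <- diag(2); dimnames(S_ok) <- list(c("x", "y"), c("x", "y"))
  expect_error(fit_ml(S_ok, m, 2), "exceed")
  expect_error(fit_ml(unname(S_ok), m, 50), "dimnames")
  expect_error(path_model(data.frame(from = "x", to = "y"),
                          covariances = data.frame(a = "x", b = "y")),
               "exogenous")
})
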