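#' Model-implied covariance matrix
#'
#' For a recursive linear system `x = A x + e` with coefficient matrix `A`
#' (rows = targets, columns = sources) and exogenous/error (co)variance
#' matrix `Omega`, the implied covariance of the observed variables is
#' `Sigma = (I - A)^{-1} Omega (I - A)^{-T}`.
#'
#' @param model a [path_model()].
#' @param theta named numeric vector of free-parameter values; names follow
#'   the `"from->to"`, `"var(x)"`, `"cov(a,b)"` convention (see
#'   [fit_ml()]); fixed values are taken from the model.
#' @return A symmetric p x p matrix with variable dimnames.
#' @examples
#' m <- path_model(data.frame(from = "x", to = "y"))
#' implied_covariance(m, c("x->y" = 0.5, "var(x)" = 1, "var(y)" = 0.75))
#' @export
implied_covariance <- function(model, theta) {
  A <- coef_matrix(model, theta)
  Omega <- omega_matrix(model, theta)
  p <- length(model$variables)
  IA <- diag(p) - A
  B <- solve(IA)
  S <- B %*% Omega %*% t(B)
  dimnames(S) <- list(model$variables, model$variables)
  (S + t(S)) / 2
}

# Omega: exogenous variances/covariances plus error variances, from theta
# (free) and the model (fixed covariances).
omega_matrix <- function(model, theta) {
  p <- length(model$variables)
  O <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  for (v in model$variables) {
    nm <- paste0("var(", v, ")")
    if (!(nm %in% names(theta)) || is.na(theta[[nm]])) {
      stop("no value for variance parameter ", nm)
    }
    O[v, v] <- theta[[nm]]
  }
  cvs <- model$covariances
  for (i in seq_len(nrow(cvs))) {
    val <- cvs$fixed[i]
    if (is.na(val)) val <- theta[[paste0("cov(", cvs$a[i], ",", cvs$b[i], ")")]]
    O[cvs$a[i], cvs$b[i]] <- O[cvs$b[i], cvs$a[i]] <- val
  }
  O
}

# ML discrepancy F(Sigma; S) = log|Sigma| + tr(S Sigma^-1) - log|S| - p.
ml_discrepancy <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  logdet + tr - logdetS - nrow(S)
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F(theta) = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters by quasi-Newton (BFGS) with analytic gradients.
#' Variances are optimized on the log scale to keep them positive.  Five
#' deterministic starts are used, the first being a per-equation
#' least-squares warm start; the remainder rescale its coefficients.  At the
#' optimum the classical chi-square statistic is `(n - 1) * F`, with
#' `df = p(p+1)/2 - q` degrees of freedom.
#'
#' @param S sample covariance matrix (n - 1 denominator) with dimnames
#'   covering the model variables.
#' @param model a [path_model()].
#' @param n number of observations behind `S`.
#' @param n_starts number of deterministic starts (default 5).
#' @param grad_tol gradient max-norm required to declare convergence.
#' @param se compute standard errors from the inverse observed information
#'   (numerical Hessian)?  Skipping them (`se = FALSE`) makes large
#'   candidate sweeps much cheaper; estimates and fit statistics are
#'   unaffected.
#' @return An object of class `sem_fit`: a list with the estimates
#'   (`$estimates`, natural scale), `$coef_table` (per-edge estimate, SE, z,
#'   two-sided p, standardized coefficient), `$std_coefficients`, `$sigma`
#'   (fitted covariance), `$chisq`, `$df`, `$p_value`, `$bcc`, `$aic`,
#'   `$r2` (per endogenous variable), `$converged` and `$heywood` flags.
#' @references Bollen, K. A. (1989) Structural Equations with Latent
#'   Variables. Wiley.  Browne, M. W. and Cudeck, R. (1989) Single sample
#'   cross-validation indices for covariance structures.
#' @export
fit_ml <- function(S, model, n, n_starts = 5, grad_tol = 1e-8, se = TRUE) {
  vars <- model$variables
  if (is.null(dimnames(S)) || !all(vars %in% rownames(S))) {
    stop("S must have dimnames covering the model variables")
  }
  S <- as.matrix(S)[vars, vars]
  S <- (S + t(S)) / 2
  p <- length(vars)
  if (n <= p) stop("n must exceed the number of variables")
  chS <- tryCatch(chol(S), error = function(e) {
    stop("sample covariance matrix is not positive definite")
  })
  logdetS <- 2 * sum(log(diag(chS)))
  fp <- free_param_names(model)
  q <- length(fp$coef) + length(fp$var) + length(fp$cov)
  df <- as.integer(p * (p + 1) / 2 - q)
  if (df < 0) stop("model is not identified (negative degrees of freedom)")

  # Optimize in the correlation metric: F_ML is invariant under separate
  # rescaling of the observed variables, and unit scales keep the
  # quasi-Newton steps well conditioned when raw variances differ by
  # orders of magnitude.  Fixed values are mapped into the scaled space
  # and all estimates are mapped back afterwards.
  D <- sqrt(diag(S))
  S_raw <- S
  logdetS_raw <- logdetS
  S <- S / tcrossprod(D)
  logdetS <- 2 * sum(log(diag(chol(S))))
  model_sc <- model
  e_sc <- model_sc$edges
  for (i in seq_len(nrow(e_sc))) {
    if (!is.na(e_sc$fixed[i])) {
      e_sc$fixed[i] <- e_sc$fixed[i] * D[e_sc$from[i]] / D[e_sc$to[i]]
    }
  }
  model_sc$edges <- e_sc
  cv_sc <- model_sc$covariances
  for (i in seq_len(nrow(cv_sc))) {
    if (!is.na(cv_sc$fixed[i])) {
      cv_sc$fixed[i] <- cv_sc$fixed[i] / (D[cv_sc$a[i]] * D[cv_sc$b[i]])
    }
  }
  model_sc$covariances <- cv_sc
  model_fit <- model
  model <- model_sc

  warm <- ols_warm_start(S, model)
  pack <- function(theta) {
    c(theta[fp$coef], log(pmax(theta[fp$var], 1e-10)), theta[fp$cov])
  }
  unpack <- function(eta) {
    theta <- stats::setNames(numeric(q), c(fp$coef, fp$var, fp$cov))
    nc <- length(fp$coef); nv <- length(fp$var)
    if (nc) theta[fp$coef] <- eta[seq_len(nc)]
    theta[fp$var] <- exp(eta[nc + seq_len(nv)])
    if (length(fp$cov)) theta[fp$cov] <- eta[nc + nv + seq_along(fp$cov)]
    theta
  }

  obj <- function(eta) {
    theta <- unpack(eta)
    Sigma <- tryCatch(implied_covariance(model, theta),
                      error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    f <- ml_discrepancy(Sigma, S, logdetS)
    if (!is.finite(f)) f <- 1e10
    f
  }
  grad <- function(eta) {
    theta <- unpack(eta)
    A <- coef_matrix(model, theta)
    Omega <- omega_matrix(model, theta)
    B <- tryCatch(solve(diag(p) - A), error = function(e) NULL)
    if (is.null(B)) return(numeric_grad(obj, eta))
    Sigma <- B %*% Omega %*% t(B)
    ch <- tryCatch(chol((Sigma + t(Sigma)) / 2), error = function(e) NULL)
    if (is.null(ch)) return(numeric_grad(obj, eta))
    Sinv <- chol2inv(ch)
    W <- Sinv - Sinv %*% S %*% Sinv
    GA <- 2 * t(B) %*% W %*% Sigma          # d F / d A[r, c] at [r, c]
    GO <- t(B) %*% W %*% B                  # d F / d Omega
    g <- numeric(q)
    names(g) <- c(fp$coef, fp$var, fp$cov)
    for (nm in fp$coef) {
      ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
      g[nm] <- GA[ft[2], ft[1]]
    }
    for (nm in fp$var) {
      v <- sub("^var\\(", "", sub("\\)$", "", nm))
      g[nm] <- GO[v, v] * theta[[nm]]       # chain rule, log scale
    }
    for (nm in fp$cov) {
      ab <- strsplit(sub("^cov\\(", "", sub("\\)$", "", nm)), ",")[[1]]
      g[nm] <- 2 * GO[ab[1], ab[2]]
    }
    g
  }

  scales <- c(1, 0, 0.5, 1.5, -0.5)[seq_len(max(1, n_starts))]
  best <- NULL
  for (s in scales) {
    start <- warm
    start[fp$coef] <- warm[fp$coef] * s
    eta <- pack(start)
    opt <- stats::optim(eta, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    # BFGS restarts sharpen the gradient norm at negligible cost
    for (k in 1:3) {
      if (max(abs(grad(opt$par))) <= grad_tol) break
      opt2 <- stats::optim(opt$par, obj, grad, method = "BFGS",
                           control = list(maxit = 500, reltol = 1e-14))
      if (opt2$value <= opt$value) opt <- opt2 else break
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  theta <- unpack(best$par)
  gnorm <- max(abs(grad(best$par)))

  # standard errors: inverse observed information, computed in the
  # well-conditioned scaled space and mapped back with the parameters
  se_vec <- rep(NA_real_, q)
  names(se_vec) <- names(theta)
  if (se) {
    nm_theta <- names(theta)
    H <- numeric_hessian(function(th) {
      Sg <- tryCatch(
        implied_covariance(model, stats::setNames(th, nm_theta)),
        error = function(e) NULL)
      if (is.null(Sg)) return(1e10)
      f <- ml_discrepancy(Sg, S, logdetS)
      if (!is.finite(f)) 1e10 else f
    }, as.numeric(theta))
    acov <- tryCatch(solve(H) * 2 / (n - 1), error = function(e) NULL)
    if (!is.null(acov)) {
      d <- diag(acov)
      se_vec[d > 0] <- sqrt(d[d > 0])
    }
  }

  # back to the natural scale (same factors for estimates and SEs)
  model <- model_fit
  S <- S_raw
  logdetS <- logdetS_raw
  fac <- stats::setNames(rep(1, q), names(theta))
  for (nm in fp$coef) {
    ft <- strsplit(nm, "->", fixed = TRUE)[[1]]
    fac[nm] <- D[ft[2]] / D[ft[1]]
  }
  for (nm in fp$var) {
    v <- sub("^var\\(", "", sub("\\)$", "", nm))
    fac[nm] <- D[v]^2
  }
  for (nm in fp$cov) {
    ab <- strsplit(sub("^cov\\(", "", sub("\\)$", "", nm)), ",")[[1]]
    fac[nm] <- D[ab[1]] * D[ab[2]]
  }
  theta <- theta * fac
  se_vec <- se_vec * fac
  Sigma <- implied_covariance(model, theta)
  Fmin <- ml_discrepancy(Sigma, S, logdetS)
  chisq <- max(0, (n - 1) * Fmin)
  pval <- if (df >= 1) stats::pchisq(chisq, df, lower.tail = FALSE)
          else NA_real_

  # improper solution: an error variance collapsing to (numerical) zero
  # relative to its own variable's variance
  err_var <- if (length(model$endogenous))
    theta[paste0("var(", model$endogenous, ")")] else numeric(0)
  heywood <- length(err_var) > 0 &&
    any(err_var < 1e-7 * diag(S)[model$endogenous])

  sds <- sqrt(diag(Sigma))
  e <- model$edges
  est_edge <- vapply(seq_len(nrow(e)), function(i) {
    if (!is.na(e$fixed[i])) e$fixed[i]
    else theta[[paste0(e$from[i], "->", e$to[i])]]
  }, numeric(1))
  std_edge <- est_edge * sds[e$from] / sds[e$to]
  names(std_edge) <- edge_keys(e)
  se_edge <- ifelse(is.na(e$fixed), se_vec[paste0(e$from, "->", e$to)],
                    NA_real_)
  z <- est_edge / se_edge
  coef_table <- data.frame(
    from = e$from, to = e$to, estimate = est_edge, se = se_edge, z = z,
    p_value = 2 * stats::pnorm(-abs(z)), std = std_edge,
    row.names = NULL)

  r2 <- 1 - err_var / diag(Sigma)[model$endogenous]
  names(r2) <- model$endogenous

  structure(list(
    model = model, n = n, estimates = theta, se = se_vec,
    coef_table = coef_table, std_coefficients = std_edge,
    sigma = Sigma, sample_cov = S,
    chisq = chisq, df = df, p_value = pval,
    bcc = bcc(chisq, q, n, p), aic = chisq + 2 * q,
    q = q, r2 = r2, gradient_norm = gnorm,
    converged = gnorm <= max(grad_tol, 1e-6), heywood = heywood),
    class = "sem_fit")
}

# Per-equation least-squares warm start (exact ML for plain recursive
# models; a good neighbourhood otherwise).
ols_warm_start <- function(S, model) {
  fp <- free_param_names(model)
  theta <- stats::setNames(numeric(0), character(0))
  e <- model$edges
  for (v in model$variables) {
    parents <- e$from[e$to == v]
    if (length(parents) == 0) {
      theta[paste0("var(", v, ")")] <- S[v, v]
      next
    }
    b <- tryCatch(
      solve(S[parents, parents, drop = FALSE], S[parents, v]),
      error = function(err) rep(0, length(parents)))
    fixed <- e$fixed[e$to == v]
    b[!is.na(fixed)] <- fixed[!is.na(fixed)]
    rv <- S[v, v] - 2 * sum(b * S[parents, v]) +
      drop(t(b) %*% S[parents, parents, drop = FALSE] %*% b)
    theta[paste0("var(", v, ")")] <- max(rv, 0.05 * S[v, v])
    free <- is.na(fixed)
    if (any(free)) {
      theta[paste0(parents[free], "->", v)] <- b[free]
    }
  }
  cvs <- model$covariances
  for (i in seq_len(nrow(cvs))) {
    if (is.na(cvs$fixed[i])) {
      theta[paste0("cov(", cvs$a[i], ",", cvs$b[i], ")")] <-
        S[cvs$a[i], cvs$b[i]]
    }
  }
  theta[c(fp$coef, fp$var, fp$cov)]
}

numeric_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

numeric_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- xpp[c(i, j)] + h * c(1, 1)
      xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
      xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
      xmm[c(i, j)] <- xmm[c(i, j)] - h * c(1, 1)
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h^2
      } else {
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
      }
    }
  }
  H
}

#' Fit a path model to raw data
#'
#' Convenience wrapper around [fit_ml()]: computes the sample covariance
#' matrix (n - 1 denominator) of the model variables and fits.
#'
#' @param data data frame containing the model variables.
#' @param model a [path_model()].
#' @param ... passed to [fit_ml()].
#' @return A `sem_fit` object.
#' @export
fit_sem <- function(data, model, ...) {
  cols <- model$variables
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("data lacks variables: ", paste(miss, collapse = ", "))
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  fit_ml(stats::cov(d), model, n = nrow(d), ...)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "SEM fit: %d variables, n = %d, chisq = %.3f, df = %d, p = %s\n",
    length(x$model$variables), x$n, x$chisq, x$df,
    if (is.na(x$p_value)) "-" else sprintf("%.3f", x$p_value)))
  cat(sprintf("BCC = %.2f, AIC = %.2f, q = %d%s%s\n", x$bcc, x$aic, x$q,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$heywood) " [HEYWOOD]" else ""))
  tab <- x$coef_table
  tab$estimate <- round(tab$estimate, 3)
  tab$se <- round(tab$se, 3)
  tab$z <- round(tab$z, 2)
  tab$p_value <- signif(tab$p_value, 2)
  tab$std <- round(tab$std, 3)
  print(tab, row.names = FALSE)
  if (length(x$r2)) {
    cat("R2:", paste(sprintf("%s = %.2f", names(x$r2), x$r2),
                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' Upper-tail p-value of the model chi-square statistic
#'
#' @param chisq chi-square statistic (>= 0).
#' @param df degrees of freedom; for `df = 0` (saturated model) the p-value
#'   is undefined and `NA` is returned.
#' @return Upper-tail probability of the central chi-square distribution.
#' @examples
#' chisq_pvalue(2.0, 3)   # 0.572
#' chisq_pvalue(18.2, 5)  # 0.0027
#' @export
chisq_pvalue <- function(chisq, df) {
  stopifnot(chisq >= 0, df >= 0, df == round(df))
  if (df == 0) return(NA_real_)
  stats::pchisq(chisq, df, lower.tail = FALSE)
}

#' Browne-Cudeck criterion
#'
#' Single-group covariance-structure form: `BCC = chisq + 2 q (n-1)/(n-p-2)`
#' for `q` free parameters, sample size `n` and `p` observed variables.
#' The per-parameter penalty `2(n-1)/(n-p-2)` exceeds the AIC's 2 for every
#' admissible `n`, so the BCC penalizes complex models somewhat more
#' strongly.  Lower is better.
#'
#' @param chisq model chi-square.
#' @param q number of free parameters.
#' @param n sample size.
#' @param p number of observed variables.
#' @return The criterion value.
#' @export
bcc <- function(chisq, q, n, p) {
  if (n <= p + 2) stop("BCC requires n > p + 2")
  chisq + 2 * q * (n - 1) / (n - p - 2)
}

#' Standardized path coefficients of a fit
#'
#' Each raw coefficient is rescaled by `SD(source)/SD(target)` using the
#' model-implied standard deviations, giving effects in standard-deviation
#' units that are comparable across paths.
#'
#' @param fit a `sem_fit`.
#' @return Named numeric vector (`"from->to"`).
#' @export
standardized_coefficients <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  fit$std_coefficients
}

#' R-squared of an endogenous variable
#'
#' `1 - error variance / implied variance`: the share of a variable's
#' implied variance explained by its predictors.  A variable with no
#' incoming edges has nothing explained and returns 0.
#'
#' @param fit a `sem_fit`.
#' @param variable variable name; if omitted, all endogenous variables.
#' @return Numeric (vector).
#' @export
r2_endogenous <- function(fit, variable = NULL) {
  stopifnot(inherits(fit, "sem_fit"))
  if (is.null(variable)) return(fit$r2)
  if (!variable %in% fit$model$variables) {
    stop(variable, " is not a model variable")
  }
  if (!variable %in% names(fit$r2)) return(0)
  fit$r2[[variable]]
}
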