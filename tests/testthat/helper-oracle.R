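# Independent closed-form ML oracle for recursive path models.
#
# For a recursive system with uncorrelated errors the Gaussian likelihood
# factorizes over the equations, so the ML solution is available without
# iteration: each endogenous variable's coefficients are the least-squares
# solution computed from the sample covariance, its error variance is the
# corresponding residual variance, exogenous variances are the sample
# variances, and free exogenous covariances the sample covariances.  This
# route never touches the package's optimizer, so agreement between the two
# is a genuine cross-check of fit_ml.
oracle_fit_recursive <- function(S, model, n) {
  stopifnot(all(is.na(model$edges$fixed)))  # free-edge models only
  vars <- model$variables
  S <- as.matrix(S)[vars, vars]
  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  Omega <- matrix(0, p, p, dimnames = list(vars, vars))
  theta <- c()
  for (v in vars) {
    parents <- model$edges$from[model$edges$to == v]
    if (length(parents)) {
      b <- solve(S[parents, parents, drop = FALSE], S[parents, v])
      A[v, parents] <- b
      Omega[v, v] <- S[v, v] - sum(b * S[parents, v])
      theta[paste0(parents, "->", v)] <- b
    } else {
      Omega[v, v] <- S[v, v]
    }
    theta[paste0("var(", v, ")")] <- Omega[v, v]
  }
  cvs <- model$covariances
  for (i in seq_len(nrow(cvs))) {
    stopifnot(is.na(cvs$fixed[i]))
    Omega[cvs$a[i], cvs$b[i]] <- Omega[cvs$b[i], cvs$a[i]] <-
      S[cvs$a[i], cvs$b[i]]
    theta[paste0("cov(", cvs$a[i], ",", cvs$b[i], ")")] <-
      S[cvs$a[i], cvs$b[i]]
  }
  B <- solve(diag(p) - A)
  Sigma <- B %*% Omega %*% t(B)
  Fml <- log(det(Sigma)) + sum(diag(solve(Sigma, S))) - log(det(S)) - p
  sds <- sqrt(diag(Sigma))
  e <- model$edges
  std <- A[cbind(e$to, e$from)] * sds[e$from] / sds[e$to]
  names(std) <- paste0(e$from, "->", e$to)
  list(theta = theta, sigma = Sigma, chisq = max(0, (n - 1) * Fml),
       std = std)
}

# Random acyclic free-edge model over p variables (forward edges with
# probability prob), plus true standardized coefficients for sampling.
random_dag_model <- function(p, prob = 0.5, coef_range = c(0.2, 0.6)) {
  vars <- paste0("v", seq_len(p))
  from <- c(); to <- c(); val <- c()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (stats::runif(1) < prob) {
        from <- c(from, vars[i]); to <- c(to, vars[j])
        val <- c(val, sample(c(-1, 1), 1) *
                   stats::runif(1, coef_range[1], coef_range[2]))
      }
    }
  }
  if (!length(from)) {  # ensure at least one edge
    from <- vars[1]; to <- vars[2]; val <- 0.5
  }
  # shrink coefficients until every implied error variance is positive
  repeat {
    gen <- path_model(data.frame(from = from, to = to, fixed = val),
                      variables = vars)
    ok <- tryCatch({standardized_sigma(gen); TRUE},
                   error = function(e) FALSE)
    if (ok) break
    val <- val * 0.7
  }
  list(
    free = path_model(data.frame(from = from, to = to), variables = vars),
    generating = gen)
}

# Catalog entry with its fixed coefficients freed, for refitting.
free_skeleton <- function(name) {
  m <- model_catalog(name)
  e <- m$edges
  e$fixed <- NA_real_
  path_model(e, variables = m$variables,
             covariances = if (nrow(m$covariances)) m$covariances else NULL)
}
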