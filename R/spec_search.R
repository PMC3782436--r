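#' Model framework for exhaustive specification search
#'
#' A framework is a structural skeleton split into mandatory elements
#' (always present) and optional elements (each may be present or absent),
#' mirroring the way exploratory path models are built by saturating a
#' theory-based starting diagram and then searching all subsets of the
#' drawn arrows.
#'
#' @param variables character vector fixing the variable set and order.
#' @param mandatory data frame of edges (`from`, `to`, optional `fixed`)
#'   always included; may have zero rows.
#' @param optional data frame of edges searched over (each in or out).
#' @param optional_covariances optional data frame (`a`, `b`) of exogenous
#'   covariances searched over.
#' @return An object of class `model_framework`.
#' @export
model_framework <- function(variables, mandatory = NULL, optional = NULL,
                            optional_covariances = NULL) {
  empty <- data.frame(from = character(), to = character())
  if (is.null(mandatory)) mandatory <- empty
  if (is.null(optional)) optional <- empty
  if (is.null(optional_covariances)) {
    optional_covariances <- data.frame(a = character(), b = character())
  }
  key <- function(d) paste(d$from, d$to)
  if (length(intersect(key(mandatory), key(optional)))) {
    stop("mandatory and optional edge sets overlap")
  }
  # the fully saturating candidate must itself be a valid acyclic model
  all_edges <- rbind(mandatory[c("from", "to")], optional[c("from", "to")])
  path_model(all_edges, variables = variables,
             covariances = if (nrow(optional_covariances))
               optional_covariances else NULL)
  structure(list(variables = variables, mandatory = mandatory,
                 optional = optional,
                 optional_covariances = optional_covariances),
            class = "model_framework")
}

#' Enumerate all candidate models of a framework
#'
#' Generates exactly `2^k` candidates for `k` optional elements (edges plus
#' optional covariances), in deterministic lexicographic order over the
#' inclusion masks (element 1 is the least-significant bit).
#'
#' @param framework a [model_framework()].
#' @return List of [path_model()]s; each carries an integer `"mask"`
#'   attribute.
#' @export
enumerate_candidates <- function(framework) {
  ne <- nrow(framework$optional)
  nc <- nrow(framework$optional_covariances)
  k <- ne + nc
  if (k > 20) stop("more than 20 optional elements (2^k guardrail)")
  lapply(0:(2^k - 1), function(mask) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    edges <- rbind(framework$mandatory,
                   framework$optional[bits[seq_len(ne)], , drop = FALSE])
    covs <- framework$optional_covariances[
      bits[ne + seq_len(nc)], , drop = FALSE]
    m <- path_model(edges, variables = framework$variables,
                    covariances = if (nrow(covs)) covs else NULL)
    attr(m, "mask") <- mask
    m
  })
}

#' Exhaustive specification search ranked by BCC
#'
#' Fits every candidate of the framework by [fit_ml()] and ranks the
#' admissible fits by ascending BCC; ties are broken by fewer free
#' parameters, then by the lexicographic inclusion mask.  Candidates with
#' negative degrees of freedom are skipped, and non-converged or Heywood
#' solutions are excluded from the ranking and listed separately.
#'
#' @param data data frame of (transformed) observations, or `NULL` if `S`
#'   and `n` are given.
#' @param framework a [model_framework()].
#' @param S,n sample covariance and size, as an alternative to `data`.
#' @param top how many top-ranked models to keep fits for (default 10).
#' @param keep_all_fits keep every `sem_fit` (memory heavy); default keeps
#'   only the top fits.
#' @param n_starts optimizer starts per candidate during the sweep
#'   (default 2: every candidate is warm-started from its least-squares
#'   solution, so extra starts rarely change the optimum; the top models
#'   are refitted afterwards with the full start set and standard errors).
#' @return An object of class `search_result`: `$table` (one row per ranked
#'   candidate: `rank`, `mask`, `n_edges`, `q`, `df`, `chisq`, `p_value`,
#'   `bcc`, `aic`), `$fits` (named by mask, top models), `$excluded`
#'   (masks with the reason) and `$framework`.
#' @export
spec_search <- function(data = NULL, framework, S = NULL, n = NULL,
                        top = 10, keep_all_fits = FALSE, n_starts = 2) {
  if (is.null(S)) {
    vars <- framework$variables
    d <- data[vars]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    S <- stats::cov(d)
    n <- nrow(d)
  }
  cands <- enumerate_candidates(framework)
  rows <- list()
  fits <- list()
  excluded <- list()
  for (m in cands) {
    mask <- attr(m, "mask")
    if (model_df(m) < 0) {
      excluded[[length(excluded) + 1]] <-
        data.frame(mask = mask, reason = "not identified (df < 0)")
      next
    }
    fit <- tryCatch(fit_ml(S, m, n, n_starts = n_starts, se = FALSE),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      excluded[[length(excluded) + 1]] <-
        data.frame(mask = mask, reason = conditionMessage(fit))
      next
    }
    if (!fit$converged || fit$heywood) {
      excluded[[length(excluded) + 1]] <- data.frame(
        mask = mask,
        reason = if (fit$heywood) "Heywood solution" else "not converged")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      mask = mask, n_edges = nrow(m$edges), q = fit$q, df = fit$df,
      chisq = fit$chisq, p_value = fit$p_value, bcc = fit$bcc,
      aic = fit$aic)
    fits[[as.character(mask)]] <- fit
  }
  if (!length(rows)) stop("all candidate models failed to fit")
  tab <- do.call(rbind, rows)
  ord <- order(tab$bcc, tab$q, tab$mask)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  row.names(tab) <- NULL
  keep <- if (keep_all_fits) tab$mask else utils::head(tab$mask, top)
  kept <- fits[as.character(keep)]
  # refit the reported models with the full start set and standard errors
  masks <- vapply(cands, attr, integer(1), "mask")
  for (mk in as.character(utils::head(tab$mask, top))) {
    m <- cands[[which(masks == as.integer(mk))]]
    kept[[mk]] <- fit_ml(S, m, n)
  }
  structure(list(
    table = tab,
    fits = kept,
    excluded = if (length(excluded)) do.call(rbind, excluded)
               else data.frame(mask = integer(), reason = character()),
    framework = framework, n = n),
    class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Specification search: %d candidates ranked, %d excluded\n",
              nrow(x$table), nrow(x$excluded)))
  tab <- utils::head(x$table, 10)
  tab$chisq <- round(tab$chisq, 2)
  tab$p_value <- round(tab$p_value, 3)
  tab$bcc <- round(tab$bcc, 2)
  tab$aic <- round(tab$aic, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
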