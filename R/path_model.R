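#' Specify a recursive path model
#'
#' A `path_model` is the directed-edge specification of a linear-Gaussian
#' structural equation system over observed variables: regression arrows
#' (free, or fixed at a value), one error variance per endogenous variable,
#' a free variance per exogenous variable, and optional covariances between
#' exogenous variables.  The directed part must be acyclic.
#'
#' Variables with at least one incoming arrow are endogenous; all others are
#' exogenous.  Exogenous variables are uncorrelated unless a covariance is
#' declared, matching the convention under which the degrees of freedom of
#' the fitted models in [model_catalog()] were counted.
#'
#' @param edges data frame with columns `from`, `to` and optionally `fixed`
#'   (numeric; `NA` = free coefficient) and `source` (provenance label).
#' @param variables optional character vector giving the variable order;
#'   defaults to order of first appearance in `edges`.
#' @param covariances optional data frame with columns `a`, `b` and
#'   optionally `fixed` (`NA` = free) declaring exogenous covariances.
#' @return An object of class `path_model`.
#' @seealso [read_path_model()], [fit_ml()], [path_effects()]
#' @examples
#' m <- path_model(data.frame(from = c("x", "z"), to = c("y", "y")))
#' m
#' @export
path_model <- function(edges, variables = NULL, covariances = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  } else {
    edges <- data.frame(from = character(), to = character())
  }
  if (is.null(edges$fixed)) edges$fixed <- rep(NA_real_, nrow(edges))
  if (is.null(edges$source)) edges$source <- rep(NA_character_, nrow(edges))
  if (is.null(variables)) {
    variables <- unique(c(rbind(edges$from, edges$to)))
  }
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stop("duplicate variable names")
  if (!all(c(edges$from, edges$to) %in% variables)) {
    stop("edge endpoints must be listed variables")
  }
  if (anyDuplicated(edges[c("from", "to")])) stop("duplicate edges")
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (any(!is.na(edges$fixed) & !is.finite(edges$fixed))) {
    stop("fixed coefficients must be finite")
  }
  if (is.null(covariances)) {
    covariances <- data.frame(a = character(), b = character(),
                              fixed = numeric())
  }
  if (is.null(covariances$fixed)) {
    covariances$fixed <- rep(NA_real_, nrow(covariances))
  }
  covariances$a <- as.character(covariances$a)
  covariances$b <- as.character(covariances$b)

  endo <- unique(edges$to)
  exo <- setdiff(variables, endo)
  if (nrow(covariances) > 0) {
    if (any(covariances$a == covariances$b)) {
      stop("covariance entries must pair two distinct variables")
    }
    if (!all(c(covariances$a, covariances$b) %in% exo)) {
      stop("covariances are allowed between exogenous variables only")
    }
    key <- apply(covariances[c("a", "b")], 1,
                 function(r) paste(sort(r), collapse = "~~"))
    if (anyDuplicated(key)) stop("duplicate covariance entries")
  }

  m <- structure(
    list(variables = variables, edges = edges, covariances = covariances,
         exogenous = exo, endogenous = variables[variables %in% endo]),
    class = "path_model")
  topo_sort(m)  # errors if cyclic
  m
}

#' @export
print.path_model <- function(x, ...) {
  cat("Recursive path model:", length(x$variables), "variables,",
      nrow(x$edges), "directed edges\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n", sep = "")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  if (nrow(x$edges)) {
    lab <- ifelse(is.na(x$edges$fixed), "free",
                  sprintf("fixed=%g", x$edges$fixed))
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, "  [", lab, "]",
               collapse = "\n"), "\n")
  }
  for (i in seq_len(nrow(x$covariances))) {
    cat("  ", x$covariances$a[i], " ~~ ", x$covariances$b[i], "\n", sep = "")
  }
  invisible(x)
}

# Topological order of the directed part; errors on a cycle.
topo_sort <- function(model) {
  vars <- model$variables
  indeg <- stats::setNames(integer(length(vars)), vars)
  tab <- table(model$edges$to)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  avail <- names(indeg)[indeg == 0]
  edges <- model$edges
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    kids <- edges$to[edges$from == v]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
    edges <- edges[edges$from != v, , drop = FALSE]
  }
  if (length(order) != length(vars)) stop("directed part contains a cycle")
  order
}

# Coefficient matrix A (A[to, from]) with free entries filled from `coef`
# (named "from->to") and fixed entries from the model.
coef_matrix <- function(model, coef = NULL) {
  p <- length(model$variables)
  A <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  e <- model$edges
  for (i in seq_len(nrow(e))) {
    val <- e$fixed[i]
    if (is.na(val)) {
      nm <- paste0(e$from[i], "->", e$to[i])
      if (is.null(coef) || is.na(coef[nm])) {
        stop("no value for free coefficient ", nm)
      }
      val <- coef[[nm]]
    }
    A[e$to[i], e$from[i]] <- val
  }
  A
}

# "from->to" labels; empty edge sets give character(0), not "->"
edge_keys <- function(e) {
  if (nrow(e) == 0) return(character(0))
  paste0(e$from, "->", e$to)
}

free_param_names <- function(model) {
  e <- model$edges
  cf <- edge_keys(e)[is.na(e$fixed)]
  vr <- paste0("var(", c(model$exogenous, model$endogenous), ")")
  cv <- model$covariances
  cv <- if (nrow(cv)) paste0("cov(", cv$a, ",", cv$b, ")")[is.na(cv$fixed)]
        else character(0)
  list(coef = cf, var = vr, cov = cv)
}

#' Number of free parameters of a path model
#'
#' Counts free regression coefficients, error variances (one per endogenous
#' variable), exogenous variances and free exogenous covariances -- the `q`
#' entering the model degrees of freedom `p(p+1)/2 - q` and the information
#' criteria.
#'
#' @param model a [path_model()].
#' @return Integer count.
#' @export
n_free_params <- function(model) {
  fp <- free_param_names(model)
  length(fp$coef) + length(fp$var) + length(fp$cov)
}

#' Model degrees of freedom
#'
#' Covariance-structure degrees of freedom, `p(p+1)/2 - q` for `p` observed
#' variables and `q` free parameters.  Zero for a saturated model.
#'
#' @inheritParams n_free_params
#' @return Integer (can be negative for non-identified specifications).
#' @export
model_df <- function(model) {
  p <- length(model$variables)
  as.integer(p * (p + 1) / 2 - n_free_params(model))
}

#' Read a path model from a declarative spec file
#'
#' The format is line based:
#' \preformatted{
#'   # comment
#'   vars nino onset duration rainfall tc
#'   onset -> duration
#'   duration -> rainfall fixed=0.46 source=reported
#'   cov nino ~~ onset
#' }
#' `vars` (optional) fixes the variable order; edge lines accept
#' `fixed=<value>` and `source=<label>` annotations; `cov a ~~ b` declares an
#' exogenous covariance (optionally `fixed=<value>`).
#'
#' @param path file path.
#' @return A [path_model()]; the `source` annotations are kept in
#'   `$edges$source`.
#' @export
read_path_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  variables <- NULL
  ed <- list()
  cv <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "vars") {
      variables <- tok[-1]
    } else if (tok[1] == "cov") {
      if (length(tok) < 4 || tok[3] != "~~") stop("bad cov line: ", ln)
      fixed <- NA_real_
      for (t in tok[-(1:4)]) {
        if (startsWith(t, "fixed=")) fixed <- as.numeric(sub("fixed=", "", t))
      }
      cv[[length(cv) + 1]] <- data.frame(a = tok[2], b = tok[4], fixed = fixed)
    } else {
      if (length(tok) < 3 || tok[2] != "->") stop("bad edge line: ", ln)
      fixed <- NA_real_
      src <- NA_character_
      for (t in tok[-(1:3)]) {
        if (startsWith(t, "fixed=")) fixed <- as.numeric(sub("fixed=", "", t))
        if (startsWith(t, "source=")) src <- sub("source=", "", t)
      }
      ed[[length(ed) + 1]] <- data.frame(from = tok[1], to = tok[3],
                                         fixed = fixed, source = src)
    }
  }
  edges <- if (length(ed)) do.call(rbind, ed)
           else data.frame(from = character(), to = character())
  covs <- if (length(cv)) do.call(rbind, cv) else NULL
  path_model(edges, variables = variables, covariances = covs)
}

#' Write a path model to the declarative spec format
#'
#' @param model a [path_model()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_path_model <- function(model, path) {
  out <- c(paste("vars", paste(model$variables, collapse = " ")))
  e <- model$edges
  for (i in seq_len(nrow(e))) {
    ln <- paste(e$from[i], "->", e$to[i])
    if (!is.na(e$fixed[i])) ln <- paste0(ln, " fixed=", format(e$fixed[i]))
    if (!is.na(e$source[i])) ln <- paste0(ln, " source=", e$source[i])
    out <- c(out, ln)
  }
  cvs <- model$covariances
  for (i in seq_len(nrow(cvs))) {
    ln <- paste("cov", cvs$a[i], "~~", cvs$b[i])
    if (!is.na(cvs$fixed[i])) ln <- paste0(ln, " fixed=", format(cvs$fixed[i]))
    out <- c(out, ln)
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a fitted model as a Graphviz DOT diagram
#'
#' Edges are labelled with standardized coefficients and drawn with the line
#' weights conventionally used for significance tiers in published path
#' diagrams: dashed for non-significant, and increasing pen widths for
#' p <= 0.10 (gray), 0.05, 0.01 and 0.001.
#'
#' @param fit a [sem_fit][fit_ml()] object, or a `path_model` whose edges are
#'   all fixed (a catalog entry), in which case no significance information
#'   is drawn.
#' @param path optional file to write to.
#' @return The DOT source as a character vector, invisibly if `path` given.
#' @export
sem_dot <- function(fit, path = NULL) {
  if (inherits(fit, "sem_fit")) {
    model <- fit$model
    lab <- sprintf("%.2f", fit$std_coefficients)
    pv <- fit$coef_table$p_value[match(
      paste0(model$edges$from, "->", model$edges$to),
      paste0(fit$coef_table$from, "->", fit$coef_table$to))]
    style <- vapply(pv, function(p) {
      if (is.na(p)) "solid\", penwidth=\"1"
      else if (p <= 0.001) "solid\", penwidth=\"3"
      else if (p <= 0.01) "solid\", penwidth=\"2.2"
      else if (p <= 0.05) "solid\", penwidth=\"1.4"
      else if (p <= 0.10) "solid\", color=\"gray\", penwidth=\"1.2"
      else "dashed\", penwidth=\"1"
    }, character(1))
  } else {
    model <- fit
    lab <- ifelse(is.na(model$edges$fixed), "",
                  sprintf("%.2f", model$edges$fixed))
    style <- rep("solid\", penwidth=\"1", nrow(model$edges))
  }
  lines <- c("digraph sem {", "  rankdir=LR;",
             paste0("  \"", model$variables, "\";"))
  for (i in seq_len(nrow(model$edges))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%s\", style=\"%s\"];",
      model$edges$from[i], model$edges$to[i], lab[i], style[i]))
  }
  for (i in seq_len(nrow(model$covariances))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [dir=both, style=\"dotted\"];",
      model$covariances$a[i], model$covariances$b[i]))
  }
  lines <- c(lines, "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
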