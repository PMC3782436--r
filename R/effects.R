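#' Direct, indirect and total standardized effects
#'
#' For an acyclic system with standardized coefficient matrix `A`, the
#' direct effect of a source on a target is the edge coefficient, the total
#' effect is the corresponding entry of `(I - A)^{-1} - I` (the sum over all
#' directed paths of the products of coefficients along each path), and the
#' indirect effect is their difference -- equivalently
#' `(I - A)^{-1} - I - A`.  An indirect effect over a single two-edge path
#' is just the product of its two coefficients, which is how published path
#' diagrams are usually read.
#'
#' @param x a fitted `sem_fit` (standardized coefficients are used) or a
#'   [path_model()] whose edges all carry fixed (standardized) values, e.g.
#'   a [model_catalog()] entry.
#' @param source,target optional variable names to filter the table.
#' @return A data frame with one row per ordered variable pair: `from`,
#'   `to`, `direct`, `indirect`, `total`.  Unconnected pairs have all three
#'   effects zero.
#' @examples
#' m <- model_catalog("dry_best")
#' subset(path_effects(m), from == "onset" & to == "rainfall")
#' @export
path_effects <- function(x, source = NULL, target = NULL) {
  A <- std_coef_matrix(x)
  p <- nrow(A)
  total <- solve(diag(p) - A) - diag(p)
  indirect <- total - A
  vars <- rownames(A)
  grid <- expand.grid(from = vars, to = vars, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  out <- data.frame(
    from = grid$from, to = grid$to,
    direct = A[cbind(grid$to, grid$from)],
    indirect = indirect[cbind(grid$to, grid$from)],
    total = total[cbind(grid$to, grid$from)],
    row.names = NULL)
  if (!is.null(source)) out <- out[out$from %in% source, ]
  if (!is.null(target)) out <- out[out$to %in% target, ]
  row.names(out) <- NULL
  out
}

# Standardized coefficient matrix A[to, from] from a fit or a
# fixed-coefficient model.
std_coef_matrix <- function(x) {
  if (inherits(x, "sem_fit")) {
    model <- x$model
    vals <- x$std_coefficients
  } else if (inherits(x, "path_model")) {
    model <- x
    if (anyNA(model$edges$fixed)) {
      stop("path_model passed to effect routines must have all ",
           "coefficients fixed; fit it first or use a catalog entry")
    }
    vals <- stats::setNames(model$edges$fixed, edge_keys(model$edges))
  } else {
    stop("x must be a sem_fit or a path_model")
  }
  p <- length(model$variables)
  A <- matrix(0, p, p, dimnames = list(model$variables, model$variables))
  e <- model$edges
  if (nrow(e)) A[cbind(e$to, e$from)] <- vals[edge_keys(e)]
  A
}

#' Enumerate directed paths and their coefficient products
#'
#' Lists every directed path from `source` to `target` and the product of
#' the (standardized) coefficients along it.  The sum of the products over
#' paths of length >= 2 equals the indirect effect reported by
#' [path_effects()]; individual products are the per-route contributions
#' quoted when a mediation arithmetic is written out (e.g. "-0.69 x 0.46 =
#' -0.32").
#'
#' @inheritParams path_effects
#' @param source,target variable names.
#' @return Data frame with columns `path` (arrow-joined variable names),
#'   `length` (number of edges) and `product`.
#' @export
path_products <- function(x, source, target) {
  A <- std_coef_matrix(x)
  vars <- rownames(A)
  if (!source %in% vars || !target %in% vars) {
    stop("source and target must be model variables")
  }
  res <- list()
  walk <- function(node, path, prod) {
    if (node == target && length(path) > 1) {
      res[[length(res) + 1]] <<- data.frame(
        path = paste(path, collapse = " -> "),
        length = length(path) - 1L, product = prod)
      return()
    }
    kids <- vars[A[, node] != 0]
    for (k in kids) {
      if (k %in% path) next  # acyclic anyway; belt and braces
      walk(k, c(path, k), prod * A[k, node])
    }
  }
  walk(source, source, 1)
  if (!length(res)) {
    return(data.frame(path = character(), length = integer(),
                      product = numeric()))
  }
  out <- do.call(rbind, res)
  out[order(out$length, out$path), , drop = FALSE]
}
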