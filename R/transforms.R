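#' Reflected log transform for R-squared scores
#'
#' `y = |ln(1 - x)|`, the reflect / log / re-reflect normalization for
#' heavily negatively skewed scores bounded in `[0, 1)` such as trend
#' consistency.  Strictly increasing on its domain, zero at zero.
#'
#' @param x numeric in `[0, 1)`.
#' @return Transformed values, `>= 0`.
#' @examples
#' reflect_ln(c(0, 1 - exp(-1), 0.99))  # 0, 1, ~4.605
#' @export
reflect_ln <- function(x) {
  if (any(x < 0 | x >= 1)) stop("reflect_ln requires 0 <= x < 1")
  abs(log(1 - x))
}

#' Inverse of [reflect_ln()]
#' @param y numeric `>= 0`.
#' @return `1 - exp(-y)`.
#' @export
reflect_ln_inv <- function(y) {
  if (any(y < 0)) stop("inverse domain is y >= 0")
  1 - exp(-y)
}

transform_funs <- list(
  identity   = list(f = function(x) x, inv = function(y) y,
                    domain = function(x) rep(TRUE, length(x))),
  sqrt       = list(f = sqrt, inv = function(y) y^2,
                    domain = function(x) x >= 0),
  ln         = list(f = log, inv = exp, domain = function(x) x > 0),
  log10      = list(f = log10, inv = function(y) 10^y,
                    domain = function(x) x > 0),
  square     = list(f = function(x) x^2, inv = sqrt,
                    domain = function(x) x >= 0),
  reflect_ln = list(f = reflect_ln, inv = reflect_ln_inv,
                    domain = function(x) x >= 0 & x < 1)
)

#' Default normality-transform assignments for the descriptor variables
#'
#' The mapping used for the Florida season/fire tables: square root for
#' fire counts and area burned (positive skew in counts), natural log for
#' wet-season duration and rainfall, log10 for dry-season onset date,
#' squaring for wet-season onset and dry-season duration (negative skew),
#' and the reflected log for trend consistency in both seasons.  Variables
#' not listed are left untransformed.
#'
#' @return Data frame with columns `variable`, `transform`.
#' @export
default_transforms <- function() {
  data.frame(
    variable = c("n_fires", "area_burned", "duration_wet", "rainfall_wet",
                 "onset_dry", "onset_wet", "duration_dry",
                 "tc_dry", "tc_wet"),
    transform = c("sqrt", "sqrt", "ln", "ln", "log10", "square", "square",
                  "reflect_ln", "reflect_ln"))
}

#' Apply normality transforms column-wise
#'
#' Applies one transform per listed variable and appends the result as
#' `<variable>_t`, preserving the original columns.  Domain violations are
#' reported with the offending row numbers.
#'
#' @param table data frame.
#' @param specs data frame with columns `variable`, `transform` (one of
#'   `identity`, `sqrt`, `ln`, `log10`, `square`, `reflect_ln`); default
#'   [default_transforms()] restricted to columns present.
#' @return `table` with transformed columns appended and a
#'   `"transforms"` attribute recording the mapping applied.
#' @export
apply_transforms <- function(table, specs = default_transforms()) {
  specs <- specs[specs$variable %in% names(table), , drop = FALSE]
  if (anyDuplicated(specs$variable)) {
    stop("exactly one transform per variable")
  }
  for (i in seq_len(nrow(specs))) {
    v <- specs$variable[i]
    tr <- specs$transform[i]
    if (!tr %in% names(transform_funs)) stop("unknown transform: ", tr)
    fun <- transform_funs[[tr]]
    x <- table[[v]]
    bad <- which(!fun$domain(x))
    if (length(bad)) {
      stop("transform ", tr, " of ", v, " violates its domain at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    table[[paste0(v, "_t")]] <- fun$f(x)
  }
  attr(table, "transforms") <- specs
  table
}

#' Shapiro-Wilk normality screen
#'
#' Contract wrapper around the standard Shapiro-Wilk routine, used to vet
#' each variable before and after transformation.
#'
#' @param values numeric sample, `3 <= n <= 5000`, non-constant.
#' @return List with `statistic` (W) and `p_value`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (stats::var(values) < .Machine$double.eps) stop("constant sample")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' Product-moment correlation with the classical test: `t = r *
#' sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric samples of equal length `n >= 3` with nonzero
#'   variance.
#' @return List with `r`, `n`, `t`, `df`, `p_value`.
#' @examples
#' # r = 0.80 on 11 years gives p = 0.003
#' pearson_p_from_r(0.80, 11)$p_value
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) < .Machine$double.eps ||
      stats::var(y) < .Machine$double.eps) {
    stop("degenerate variance")
  }
  r <- stats::cor(x, y)
  c(list(r = r), pearson_p_from_r(r, n)[-1])
}

#' @rdname pearson_with_p
#' @param r correlation coefficient.
#' @param n sample size.
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) {
    return(list(r = r, n = n, t = Inf * sign(r), df = n - 2, p_value = 0))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, n = n, t = t, df = n - 2,
       p_value = 2 * stats::pt(-abs(t), df = n - 2))
}
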