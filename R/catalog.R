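catalog_roles <- c(
  dry_start = "starting", wet_start = "starting",
  seasonal_saturated = "saturated-framework",
  fire_start = "starting", fire_saturated = "saturated-framework",
  dry_best = "fitted-best", wet_best = "fitted-best",
  dry_cessation = "fitted-best", wet_cessation = "fitted-best",
  fire_second_best = "fitted-best", fire_best = "fitted-best")

#' Catalog of reference path models
#'
#' Named path-model fixtures for the subtropical-Florida season/wildfire
#' analysis: the theory-based starting models for the dry and wet seasons
#' and for the fire regime, their saturated search frameworks, the best
#' exploratory models with their standardized coefficients, the
#' cessation-date variants, and the two leading wildfire models.  Fitted
#' entries carry fixed standardized coefficients; each edge's `source`
#' annotation distinguishes `reported` estimates (printed for the original
#' 58-year climate / 30-year fire record) from `carried` (taken over from a
#' sibling model) and `synthetic` (implementer defaults for simulation
#' only, never to be treated as ground truth).
#'
#' @param name entry name; omit to list available names.
#' @return With no argument, a character vector of entry names; otherwise a
#'   [path_model()] with attributes `"name"` and `"role"` (`starting`,
#'   `saturated-framework` or `fitted-best`).
#' @examples
#' model_catalog()
#' model_catalog("dry_best")
#' @export
model_catalog <- function(name = NULL) {
  if (is.null(name)) return(names(catalog_roles))
  if (!name %in% names(catalog_roles)) {
    stop("unknown catalog entry: ", name)
  }
  path <- system.file("extdata", "models", paste0(name, ".mod"),
                      package = "seasonsem", mustWork = TRUE)
  m <- read_path_model(path)
  attr(m, "name") <- name
  attr(m, "role") <- catalog_roles[[name]]
  m
}

#' Seasonal specification-search framework
#'
#' The saturated seasonal skeleton (full forward-ordered DAG over Nino 3.4,
#' onset, duration, rainfall and trend consistency) as a search framework.
#' By default every edge is optional, matching a specification search over
#' all drawn arrows; `mandatory = "starting"` pins the theory-based edges
#' of the given season's starting model instead.
#'
#' @param season `"dry"` or `"wet"` (which starting model supplies the
#'   mandatory edges when requested).
#' @param mandatory `"none"` (default) or `"starting"`.
#' @return A [model_framework()].
#' @export
seasonal_framework <- function(season = c("dry", "wet"),
                               mandatory = c("none", "starting")) {
  season <- match.arg(season)
  mandatory <- match.arg(mandatory)
  sat <- model_catalog("seasonal_saturated")
  edges <- sat$edges[c("from", "to")]
  if (mandatory == "none") {
    return(model_framework(sat$variables, optional = edges))
  }
  start <- model_catalog(paste0(season, "_start"))
  key <- paste(edges$from, edges$to)
  skey <- paste(start$edges$from, start$edges$to)
  model_framework(sat$variables,
                  mandatory = edges[key %in% skey, , drop = FALSE],
                  optional = edges[!key %in% skey, , drop = FALSE])
}

#' Wildfire specification-search framework
#'
#' The saturated wildfire skeleton (starting edges, saturating arrows and
#' the exogenous Nino~tc_wet covariance).  All elements optional by
#' default; `mandatory = "starting"` pins the six theory-based edges.
#'
#' @param mandatory `"none"` (default) or `"starting"`.
#' @return A [model_framework()].
#' @export
fire_framework <- function(mandatory = c("none", "starting")) {
  mandatory <- match.arg(mandatory)
  sat <- model_catalog("fire_saturated")
  edges <- sat$edges[c("from", "to")]
  covs <- sat$covariances[c("a", "b")]
  if (mandatory == "none") {
    return(model_framework(sat$variables, optional = edges,
                           optional_covariances = covs))
  }
  start <- model_catalog("fire_start")
  key <- paste(edges$from, edges$to)
  skey <- paste(start$edges$from, start$edges$to)
  model_framework(sat$variables,
                  mandatory = edges[key %in% skey, , drop = FALSE],
                  optional = edges[!key %in% skey, , drop = FALSE],
                  optional_covariances = covs)
}
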