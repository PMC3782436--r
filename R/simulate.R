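# Run code under a temporary RNG state when a seed is supplied.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Implied covariance of a standardized fixed-coefficient model
#'
#' For a path model whose edges all carry fixed standardized coefficients,
#' solves for the error variances that give every variable unit implied
#' variance and returns the full implied correlation matrix together with
#' those error variances.
#'
#' @param model a [path_model()] with no free edges (e.g. a fitted
#'   [model_catalog()] entry).  Free exogenous covariances are taken as 0;
#'   fixed ones are used as given (correlations).
#' @return List with `sigma` (p x p implied correlation matrix) and
#'   `error_var` (named, per endogenous variable).
#' @export
standardized_sigma <- function(model) {
  if (anyNA(model$edges$fixed)) stop("model has free coefficients")
  vars <- model$variables
  p <- length(vars)
  A <- coef_matrix(model)
  S <- matrix(0, p, p, dimnames = list(vars, vars))
  err <- stats::setNames(numeric(0), character(0))
  done <- character(0)
  for (v in topo_sort(model)) {
    parents <- vars[A[v, ] != 0]
    if (!length(parents)) {
      S[v, v] <- 1
      cvs <- model$covariances
      for (i in seq_len(nrow(cvs))) {
        other <- setdiff(c(cvs$a[i], cvs$b[i]), v)
        if (length(other) == 1 && other %in% done && !is.na(cvs$fixed[i])) {
          S[v, other] <- S[other, v] <- cvs$fixed[i]
        }
      }
    } else {
      b <- A[v, parents]
      for (u in done) {
        S[v, u] <- S[u, v] <- sum(b * S[parents, u])
      }
      explained <- drop(t(b) %*% S[parents, parents, drop = FALSE] %*% b)
      if (explained >= 1) {
        stop("standardized coefficients imply error variance <= 0 for ", v)
      }
      err[v] <- 1 - explained
      S[v, v] <- 1
    }
    done <- c(done, v)
  }
  list(sigma = S, error_var = err)
}

#' Sample descriptor tables from a fixed-coefficient path model
#'
#' Draws `n` multivariate-normal rows whose population covariance is the
#' standardized implied covariance of the model, for parameter-recovery and
#' search-calibration experiments.
#'
#' @param model a fully fixed [path_model()] (see [standardized_sigma()]).
#' @param n number of rows.
#' @param seed optional integer seed; the global RNG state is restored.
#' @return Data frame with one column per model variable.
#' @export
sample_from_path_model <- function(model, n, seed = NULL) {
  sig <- standardized_sigma(model)$sigma
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * ncol(sig)), n, ncol(sig))
    X <- Z %*% chol(sig)
    colnames(X) <- colnames(sig)
    as.data.frame(X)
  })
}

#' Configuration for the daily climate generator
#'
#' Defaults emulate a subtropical wet/dry climate with a May 21 mean
#' wet-season onset, an October 1 mean cessation, about-one-month (SD 30
#' days) interannual jitter on both boundaries, long-term mean seasonal
#' totals of roughly 89 cm (wet) and 42 cm (dry), an AR(1) monthly ENSO
#' index, and an ENSO modulation of dry-season rain depth.
#'
#' @param years number of season-years to characterize (one margin year is
#'   generated beyond them so the last dry season closes).
#' @param start_year first calendar year.
#' @param wet_onset_doy,wet_cessation_doy mean wet-season boundary
#'   day-of-year (141 = May 21, 274 = Oct 1 in non-leap years).
#' @param boundary_sd SD of the boundary jitter, days.
#' @param wet_p,dry_p daily probability of a rain event in each season.
#' @param wet_depth,dry_depth mean event depth, mm (gamma distributed).
#' @param gamma_shape shape of the event-depth gamma distribution.
#' @param enso_phi,enso_sd AR(1) coefficient and marginal SD of the monthly
#'   ENSO index.
#' @param coupling log-linear effect of the monthly index on dry-season
#'   event depth (0 = no ENSO teleconnection).
#' @param seed optional integer seed.
#' @return List of class `climate_config`.
#' @export
climate_config <- function(years = 58, start_year = 1950,
                           wet_onset_doy = 141, wet_cessation_doy = 274,
                           boundary_sd = 30,
                           wet_p = 0.85, dry_p = 0.35,
                           wet_depth = 890 / 134 / 0.85,
                           dry_depth = 420 / 231 / 0.35,
                           gamma_shape = 3,
                           enso_phi = 0.92, enso_sd = 0.85,
                           coupling = 0.15, seed = NULL) {
  stopifnot(years >= 1, wet_p > 0, wet_p <= 1, dry_p > 0, dry_p <= 1,
            wet_depth > 0, dry_depth > 0, gamma_shape > 0,
            enso_phi > 0, enso_phi < 1, enso_sd > 0, boundary_sd >= 0,
            wet_onset_doy < wet_cessation_doy)
  structure(as.list(environment()), class = "climate_config")
}

#' Generate a synthetic daily climate record with known season calendar
#'
#' Simulates daily rainfall whose event probability and gamma-distributed
#' event depth switch between wet and dry regimes at jittered per-year
#' boundaries, a monthly AR(1) ENSO index, and (via `coupling`) an ENSO
#' modulation of dry-season rain.  The true per-year boundaries are
#' returned so that season detection can be scored against ground truth.
#'
#' @param config a [climate_config()].
#' @return List with `series` (a [daily_series()]), `nino` (a
#'   [monthly_index()]), `truth` (data frame `year`, `wet_onset`,
#'   `wet_cessation` as `Date`s) and `config`.
#' @export
generate_daily_climate <- function(config = climate_config()) {
  stopifnot(inherits(config, "climate_config"))
  cfg <- config
  with_seed(cfg$seed, {
    yrs <- cfg$start_year:(cfg$start_year + cfg$years)  # + margin year
    ny <- length(yrs)

    # monthly AR(1) ENSO index
    nm <- ny * 12
    innov_sd <- cfg$enso_sd * sqrt(1 - cfg$enso_phi^2)
    x <- numeric(nm)
    x[1] <- stats::rnorm(1, 0, cfg$enso_sd)
    for (t in 2:nm) {
      x[t] <- cfg$enso_phi * x[t - 1] + stats::rnorm(1, 0, innov_sd)
    }
    nino <- monthly_index(rep(yrs, each = 12), rep(1:12, ny), x)

    # true season boundaries (clamped away from degenerate seasons)
    onset_doy <- round(stats::rnorm(ny, cfg$wet_onset_doy, cfg$boundary_sd))
    onset_doy <- pmin(pmax(onset_doy, 70), 205)
    cess_doy <- round(stats::rnorm(ny, cfg$wet_cessation_doy,
                                   cfg$boundary_sd))
    cess_doy <- pmin(pmax(cess_doy, 215), 355)
    truth <- data.frame(
      year = yrs,
      wet_onset = as.Date(paste0(yrs, "-01-01")) + (onset_doy - 1),
      wet_cessation = as.Date(paste0(yrs, "-01-01")) + (cess_doy - 1))

    dates <- seq(as.Date(paste0(yrs[1], "-01-01")),
                 as.Date(paste0(yrs[ny], "-12-31")), by = "day")
    yr_of <- as.integer(format(dates, "%Y"))
    iy <- match(yr_of, yrs)
    wet <- dates >= truth$wet_onset[iy] & dates <= truth$wet_cessation[iy]

    mon_of <- as.integer(format(dates, "%m"))
    nino_day <- x[(iy - 1) * 12 + mon_of]
    # mean-preserving log-linear ENSO modulation of dry-season depth
    mult <- exp(cfg$coupling * nino_day -
                  (cfg$coupling * cfg$enso_sd)^2 / 2)
    p_day <- ifelse(wet, cfg$wet_p, cfg$dry_p)
    depth_mean <- ifelse(wet, cfg$wet_depth, cfg$dry_depth * mult)
    occur <- stats::rbinom(length(dates), 1, p_day)
    depth <- stats::rgamma(length(dates), shape = cfg$gamma_shape,
                           scale = depth_mean / cfg$gamma_shape)
    series <- daily_series(dates, occur * depth)
    list(series = series, nino = nino, truth = truth, config = cfg)
  })
}

#' Configuration for the annual wildfire-record generator
#'
#' Defaults take the path structure and standardized coefficients of the
#' `fire_second_best` catalog model: previous wet-season trend consistency
#' suppresses fire number and (with ENSO-driven dry-season rainfall)
#' area burned; fire number drives area burned.  Fires are generated on the
#' square-root scale and back-transformed, with counts rounded.
#'
#' @param coefficients named numeric vector of standardized path
#'   coefficients (`"from->to"` over `nino`, `tc_wet`, `rainfall`,
#'   `n_fires`, `area`); defaults from the catalog.
#' @param noise_sd_n_fires,noise_sd_area residual SDs on the standardized
#'   square-root scale.
#' @param n_fires_mean,n_fires_sd,area_mean,area_sd location and scale used
#'   to map standardized values to the sqrt(count) and sqrt(ha) scales.
#' @param seed optional integer seed.
#' @return List of class `fire_config`.
#' @export
fire_config <- function(coefficients = NULL,
                        noise_sd_n_fires = sqrt(1 - 0.52^2),
                        noise_sd_area = 0.60,
                        n_fires_mean = 3.6, n_fires_sd = 0.8,
                        area_mean = 40, area_sd = 14, seed = NULL) {
  if (is.null(coefficients)) {
    m <- model_catalog("fire_second_best")
    coefficients <- stats::setNames(
      m$edges$fixed, paste0(m$edges$from, "->", m$edges$to))
  }
  structure(list(coefficients = coefficients,
                 noise_sd_n_fires = noise_sd_n_fires,
                 noise_sd_area = noise_sd_area,
                 n_fires_mean = n_fires_mean, n_fires_sd = n_fires_sd,
                 area_mean = area_mean, area_sd = area_sd, seed = seed),
            class = "fire_config")
}

#' Generate annual wildfire records from climate descriptors
#'
#' Takes a fire-season table (one row per fire year with the dry-season
#' Nino 3.4 mean, dry-season rainfall in cm and the previous wet season's
#' trend consistency) and generates number of fires and area burned from
#' the configured path coefficients: a linear model on the standardized
#' square-root scale plus Gaussian noise, back-transformed, counts rounded
#' and negatives truncated at zero (with a message giving the count).
#'
#' @param descriptors data frame with columns `year`, `nino`, `rainfall`,
#'   `tc_wet` (trend consistency in `[0, 1)`).
#' @param config a [fire_config()].
#' @return Data frame `year`, `n_fires`, `area_burned_ha`, with attribute
#'   `"truncated"` (number of zero-truncated values).
#' @export
generate_fire_records <- function(descriptors, config = fire_config()) {
  stopifnot(inherits(config, "fire_config"))
  need <- c("year", "nino", "rainfall", "tc_wet")
  miss <- setdiff(need, names(descriptors))
  if (length(miss)) stop("missing descriptor columns: ",
                         paste(miss, collapse = ", "))
  cf <- config$coefficients
  getc <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  with_seed(config$seed, {
    z <- function(x) as.numeric(scale(x))
    z_rain <- z(descriptors$rainfall)
    z_tcw <- z(reflect_ln(descriptors$tc_wet))
    n <- nrow(descriptors)
    z_nf <- getc("tc_wet->n_fires") * z_tcw +
      getc("rainfall->n_fires") * z_rain +
      getc("nino->n_fires") * z(descriptors$nino) +
      stats::rnorm(n, 0, config$noise_sd_n_fires)
    z_ar <- getc("rainfall->area") * z_rain +
      getc("n_fires->area") * z_nf +
      getc("tc_wet->area") * z_tcw +
      getc("nino->area") * z(descriptors$nino) +
      stats::rnorm(n, 0, config$noise_sd_area)
    sq_nf <- config$n_fires_mean + config$n_fires_sd * z_nf
    sq_ar <- config$area_mean + config$area_sd * z_ar
    truncated <- sum(sq_nf < 0) + sum(sq_ar < 0)
    if (truncated > 0) {
      message(truncated, " value(s) truncated at zero")
    }
    out <- data.frame(
      year = descriptors$year,
      n_fires = round(pmax(sq_nf, 0)^2),
      area_burned_ha = pmax(sq_ar, 0)^2)
    attr(out, "truncated") <- truncated
    out
  })
}
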