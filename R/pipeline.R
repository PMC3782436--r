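#' Per-season SEM-ready variable table
#'
#' Extracts one season's descriptors into the generic SEM variable set
#' (`nino`, `onset`, `duration`, `rainfall`, `tc`) and applies the default
#' normality transforms for that season (dry: log10 onset, squared
#' duration, reflected-log tc; wet: squared onset, log duration, log
#' rainfall, reflected-log tc).  The returned columns are on the
#' transformed scales, ready for [fit_sem()] / [spec_search()].
#'
#' @param descriptors a [build_descriptor_table()] result with a `nino34`
#'   column (see [add_seasonal_nino()]).
#' @param season `"dry"` or `"wet"`.
#' @return Data frame `year`, `nino`, `onset`, `duration`, `rainfall`,
#'   `tc`.
#' @export
season_sem_table <- function(descriptors, season = c("dry", "wet")) {
  season <- match.arg(season)
  d <- descriptors[descriptors$season == season, , drop = FALSE]
  raw <- data.frame(year = d$year, nino = d$nino34, onset = d$onset_doy,
                    duration = d$duration_days, rainfall = d$rainfall_cm,
                    tc = d$trend_r2)
  specs <- if (season == "dry") {
    data.frame(variable = c("onset", "duration", "tc"),
               transform = c("log10", "square", "reflect_ln"))
  } else {
    data.frame(variable = c("onset", "duration", "rainfall", "tc"),
               transform = c("square", "ln", "ln", "reflect_ln"))
  }
  tr <- apply_transforms(raw, specs)
  out <- data.frame(year = raw$year, nino = raw$nino)
  for (v in c("onset", "duration", "rainfall", "tc")) {
    tcol <- paste0(v, "_t")
    out[[v]] <- if (tcol %in% names(tr)) tr[[tcol]] else tr[[v]]
  }
  out
}

#' Fire-season SEM-ready table
#'
#' Assembles the wildfire model's variables for each fire year `t`: the
#' Nino 3.4 mean and rainfall of the dry season that spans the fire season
#' (the dry season labelled `t - 1`, running from autumn of `t - 1` into
#' spring of `t`), the trend consistency of the preceding wet season
#' (`t - 1`), and the fire records of year `t`.  The one-year shift drops
#' the first available year.  Transforms: reflected log for `tc_wet`,
#' square root for `n_fires` and `area`.
#'
#' @param descriptors descriptor table with `nino34` (see
#'   [add_seasonal_nino()]).
#' @param fires data frame `year`, `n_fires`, `area_burned_ha`.
#' @return Data frame `year`, `nino`, `tc_wet`, `rainfall`, `n_fires`,
#'   `area` (transformed scales).
#' @export
fire_sem_table <- function(descriptors, fires) {
  dry <- descriptors[descriptors$season == "dry", , drop = FALSE]
  wet <- descriptors[descriptors$season == "wet", , drop = FALSE]
  prev <- fires$year - 1
  i_dry <- match(prev, dry$year)
  i_wet <- match(prev, wet$year)
  ok <- !is.na(i_dry) & !is.na(i_wet)
  out <- data.frame(
    year = fires$year[ok],
    nino = dry$nino34[i_dry[ok]],
    tc_wet = reflect_ln(wet$trend_r2[i_wet[ok]]),
    rainfall = dry$rainfall_cm[i_dry[ok]],
    n_fires = sqrt(fires$n_fires[ok]),
    area = sqrt(fires$area_burned_ha[ok]))
  out
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param years,start_year season-years to characterize.
#' @param fire_years fire-record years (default the last 30 season-years).
#' @param climate a [climate_config()] override, or `NULL` to build one
#'   from `years`/`start_year`/`seed`.
#' @param rainfall_csv,nino_csv,fires_csv optional input files; when given
#'   they replace the corresponding synthetic inputs.
#' @param search_top how many top models to report per search.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("seasonsem_"), seed = 1,
                            years = 58, start_year = 1950,
                            fire_years = NULL, climate = NULL,
                            rainfall_csv = NULL, nino_csv = NULL,
                            fires_csv = NULL, search_top = 10) {
  if (is.null(fire_years)) {
    fire_years <- (start_year + years - 30):(start_year + years - 1)
  }
  structure(list(out_dir = out_dir, seed = seed, years = years,
                 start_year = start_year, fire_years = fire_years,
                 climate = climate, rainfall_csv = rainfall_csv,
                 nino_csv = nino_csv, fires_csv = fires_csv,
                 search_top = search_top),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) daily rainfall, the monthly Nino 3.4 index and
#' annual fire records; builds the CRA season-descriptor table; attaches
#' season-weighted Nino 3.4; applies the normality transforms; fits the
#' theory-based starting models; runs the exhaustive specification
#' searches for the dry, wet and fire frameworks; decomposes the effects
#' of each best model; and writes all tables (TSV), fit summaries (JSON)
#' and a provenance record to `config$out_dir`.  Deterministic for a fixed
#' config: a rerun writes byte-identical reports.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the descriptor table, the three SEM
#'   tables, starting fits, search results and best-model effect tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    message(sprintf(...))
  }

  # --- inputs ---------------------------------------------------------
  if (is.null(config$rainfall_csv) || is.null(config$nino_csv)) {
    ccfg <- config$climate
    if (is.null(ccfg)) {
      ccfg <- climate_config(years = config$years,
                             start_year = config$start_year,
                             seed = config$seed)
    }
    clim <- generate_daily_climate(ccfg)
    series <- clim$series
    nino <- clim$nino
    say("stage input: synthetic climate, %d years, seed %s",
        ccfg$years, format(ccfg$seed))
  } else {
    series <- read_daily_rainfall(config$rainfall_csv)
    nino <- read_nino34(config$nino_csv)
    say("stage input: %s, %s", config$rainfall_csv, config$nino_csv)
  }

  # --- season descriptors ---------------------------------------------
  yrs <- config$start_year:(config$start_year + config$years - 1)
  desc <- build_descriptor_table(series, years = c(yrs, max(yrs) + 1))
  desc <- desc[desc$year %in% yrs, , drop = FALSE]
  desc <- add_seasonal_nino(desc, nino)
  write_descriptor_table(desc, file.path(config$out_dir, "descriptors.tsv"))
  say("stage seasons: %d descriptor rows over %d years",
      nrow(desc), length(unique(desc$year)))

  dry_tab <- season_sem_table(desc, "dry")
  wet_tab <- season_sem_table(desc, "wet")

  # --- fire records ----------------------------------------------------
  if (is.null(config$fires_csv)) {
    dry <- desc[desc$season == "dry", ]
    wet <- desc[desc$season == "wet", ]
    prev <- config$fire_years - 1
    fd <- data.frame(year = config$fire_years,
                     nino = dry$nino34[match(prev, dry$year)],
                     rainfall = dry$rainfall_cm[match(prev, dry$year)],
                     tc_wet = wet$trend_r2[match(prev, wet$year)])
    fd <- fd[stats::complete.cases(fd), ]
    fires <- generate_fire_records(
      fd, fire_config(seed = config$seed + 1000L))
    say("stage fires: synthetic records for %d years", nrow(fires))
  } else {
    fires <- utils::read.csv(config$fires_csv)
    say("stage fires: %s", config$fires_csv)
  }
  fire_tab <- fire_sem_table(desc, fires)
  say("stage fire table: %d fire years after one-year lag (first year %s)",
      nrow(fire_tab), "dropped by the shift")

  for (nm in c("dry_tab", "wet_tab", "fire_tab")) {
    utils::write.table(get(nm), file.path(config$out_dir,
                                          paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- starting fits and searches -------------------------------------
  starts <- list(
    dry = fit_sem(dry_tab, model_catalog("dry_start")),
    wet = fit_sem(wet_tab, model_catalog("wet_start")),
    fire = fit_sem(fire_tab, model_catalog("fire_start")))
  searches <- list(
    dry = spec_search(dry_tab, seasonal_framework("dry"),
                      top = config$search_top),
    wet = spec_search(wet_tab, seasonal_framework("wet"),
                      top = config$search_top),
    fire = spec_search(fire_tab, fire_framework(),
                       top = config$search_top))
  effects <- list()
  for (nm in names(searches)) {
    sr <- searches[[nm]]
    utils::write.table(sr$table,
                       file.path(config$out_dir,
                                 paste0("search_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    best <- sr$fits[[as.character(sr$table$mask[1])]]
    effects[[nm]] <- path_effects(best)
    utils::write.table(effects[[nm]],
                       file.path(config$out_dir,
                                 paste0("effects_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(sem_fit_report(best),
                         file.path(config$out_dir,
                                   paste0("best_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("stage search %s: best mask %d (BCC %.2f, chisq %.2f, df %d)",
        nm, sr$table$mask[1], sr$table$bcc[1], sr$table$chisq[1],
        sr$table$df[1])
  }
  for (nm in names(starts)) {
    jsonlite::write_json(sem_fit_report(starts[[nm]]),
                         file.path(config$out_dir,
                                   paste0("start_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  provenance <- list(
    package = "seasonsem",
    version = as.character(utils::packageVersion("seasonsem")),
    seed = config$seed,
    years = config$years, start_year = config$start_year,
    fire_years = range(config$fire_years),
    stages = log_lines)
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(descriptors = desc, tables = list(dry = dry_tab,
                                                   wet = wet_tab,
                                                   fire = fire_tab),
                 starts = starts, searches = searches, effects = effects,
                 out_dir = config$out_dir))
}

#' Serializable summary of a fit
#'
#' @param fit a `sem_fit`.
#' @return Plain list mirroring the fit fields, suitable for JSON export.
#' @export
sem_fit_report <- function(fit) {
  list(variables = fit$model$variables,
       n = fit$n, q = fit$q, df = fit$df,
       chisq = fit$chisq, p_value = fit$p_value,
       bcc = fit$bcc, aic = fit$aic,
       converged = fit$converged, heywood = fit$heywood,
       r2 = as.list(fit$r2),
       coefficients = fit$coef_table)
}
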