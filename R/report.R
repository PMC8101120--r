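#' Configuration for a projection run
#'
#' Validated run configuration for [run_projection()].
#'
#' @param input Path to a region parameter CSV ([load_region_table()]
#'   schema), or a `region_table` already in memory.
#' @param approaches Character subset of `c("deterministic", "stochastic")`.
#' @param start_year,end_year Calendar span of the projection
#'   (`end_year > start_year`). Defaults 2017-2035.
#' @param replicates Stochastic replicates (>= 1 when the stochastic
#'   approach is requested).
#' @param seed Master seed for all randomness in the run.
#' @param closure `"stationary-healthy"` or a constant birth inflow
#'   (persons/year) applied to every region.
#' @param output_dir Directory for output files (created if absent).
#' @param thousands Report case counts in thousands to 3 decimals (default);
#'   `FALSE` reports raw persons.
#' @param verbose Log progress to `stderr`.
#' @return An object of class `projection_config`.
#' @export
projection_config <- function(input,
                              approaches = c("deterministic", "stochastic"),
                              start_year = 2017, end_year = 2035,
                              replicates = 200, seed = 1,
                              closure = "stationary-healthy",
                              output_dir = ".", thousands = TRUE,
                              verbose = FALSE) {
  approaches <- match.arg(approaches, c("deterministic", "stochastic"),
                          several.ok = TRUE)
  if (end_year <= start_year)
    stop("end_year must be greater than start_year", call. = FALSE)
  if ("stochastic" %in% approaches && (is.null(replicates) || replicates < 1))
    stop("stochastic approach requested but replicates < 1", call. = FALSE)
  if (!identical(closure, "stationary-healthy") &&
      (!is.numeric(closure) || closure < 0))
    stop("closure must be 'stationary-healthy' or a nonnegative number",
         call. = FALSE)
  if (is.character(input) && !file.exists(input))
    stop("input table not found: ", input, call. = FALSE)
  structure(list(input = input, approaches = approaches,
                 start_year = start_year, end_year = end_year,
                 replicates = replicates, seed = as.integer(seed),
                 closure = closure, output_dir = output_dir,
                 thousands = thousands, verbose = verbose),
            class = "projection_config")
}

report_log <- function(config, ...) {
  if (isTRUE(config$verbose)) message(sprintf(...))
  invisible(NULL)
}

#' Run the full projection pipeline and write report files
#'
#' For every region in the input table, runs the requested approaches over
#' `[start_year, end_year]` and writes:
#' \itemize{
#'   \item `projections.csv` — tidy rows `region, approach, year, ibd_cases,
#'     ibd_low, ibd_high`; the deterministic rows carry the UI envelope from
#'     [project_interval()], the stochastic rows the ensemble 2.5%/97.5%
#'     quantiles. Counts in thousands to 3 decimals unless
#'     `thousands = FALSE`.
#'   \item `summary.json` — per region: doubling time from the start year,
#'     fold change over the horizon, and final-year counts per approach.
#'   \item `run.log` — seed, closure, package version, input digestables.
#' }
#'
#' @param config A [projection_config()].
#' @return Invisibly, a list with the output `files` and the assembled
#'   `projections` data frame and `summary` list.
#' @export
run_projection <- function(config) {
  stopifnot(inherits(config, "projection_config"))
  tab <- if (inherits(config$input, "region_table")) config$input
         else load_region_table(config$input)
  horizon <- config$end_year - config$start_year
  scale <- if (config$thousands) 1e-3 else 1
  digits <- if (config$thousands) 3L else 1L
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); summaries <- list()
  for (p in tab) {
    if (p$start_year != config$start_year)
      p$start_year <- config$start_year  # table anchors the counts at start_year
    m <- illness_death(p, birth_inflow = config$closure)
    region_summary <- list()
    if ("deterministic" %in% config$approaches) {
      report_log(config, "projecting %s (deterministic)", p$region)
      traj <- predict(m, horizon_years = horizon)
      band <- tryCatch(project_interval(p, horizon),
                       error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        region = p$region, approach = "deterministic", year = traj$year,
        ibd_cases = round(traj$ibd * scale, digits),
        ibd_low = if (is.null(band)) NA else round(band$ibd_low * scale, digits),
        ibd_high = if (is.null(band)) NA else round(band$ibd_high * scale, digits))
      region_summary$deterministic <- list(
        final_year = config$end_year,
        final_cases = round(traj$ibd[nrow(traj)] * scale, digits),
        doubling_time_years = doubling_time(traj, config$start_year),
        fold_change = fold_change(traj, config$start_year, config$end_year))
    }
    if ("stochastic" %in% config$approaches) {
      report_log(config, "projecting %s (stochastic, %d replicates)",
                 p$region, config$replicates)
      ens <- simulate(m, nsim = config$replicates, seed = config$seed,
                      horizon_years = horizon)
      sm <- summarize_ensemble(ens)
      rows[[length(rows) + 1L]] <- data.frame(
        region = p$region, approach = "stochastic", year = sm$year,
        ibd_cases = round(sm$mean * scale, digits),
        ibd_low = round(sm$q2.5 * scale, digits),
        ibd_high = round(sm$q97.5 * scale, digits))
      smtraj <- data.frame(year = sm$year, ibd = sm$mean)
      region_summary$stochastic <- list(
        final_year = config$end_year,
        final_cases = round(sm$mean[nrow(sm)] * scale, digits),
        doubling_time_years = doubling_time(smtraj, config$start_year),
        fold_change = fold_change(smtraj, config$start_year, config$end_year))
    }
    summaries[[p$region]] <- region_summary
  }
  proj <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  files <- file.path(config$output_dir,
                     c(csv = "projections.csv", json = "summary.json",
                       log = "run.log"))
  names(files) <- c("csv", "json", "log")
  utils::write.csv(proj, files[["csv"]], row.names = FALSE, quote = TRUE)
  # Inf doubling times must survive JSON: encode as the string "never"
  enc <- rapply(summaries, function(v)
    if (is.numeric(v) && length(v) == 1 && is.infinite(v)) "never" else v,
    how = "replace")
  jsonlite::write_json(enc, files[["json"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(c(sprintf("ibdforecast %s",
                       as.character(utils::packageVersion("ibdforecast"))),
               sprintf("seed: %d", config$seed),
               sprintf("closure: %s", paste(config$closure, collapse = " ")),
               sprintf("approaches: %s", paste(config$approaches, collapse = ", ")),
               sprintf("span: %d-%d", config$start_year, config$end_year),
               sprintf("replicates: %d", config$replicates),
               sprintf("units: %s", if (config$thousands) "thousands" else "persons"),
               sprintf("regions: %s", paste(names(summaries), collapse = "; "))),
             files[["log"]])
  report_log(config, "wrote %s", paste(files, collapse = ", "))
  invisible(list(files = files, projections = proj, summary = summaries))
}

#' Generate and write a synthetic study set
#'
#' Writes a synthetic region table (same CSV schema [load_region_table()]
#' reads) and one noisy observed-prevalence series per region.
#'
#' @param spec A [synthetic_region_spec()].
#' @param n_regions Number of synthetic regions.
#' @param years Length of each observed series (calendar years).
#' @param output_dir Output directory (created if absent).
#' @return Invisibly, list with `table_file`, `series_files`, and the
#'   generated `params`.
#' @export
run_synth <- function(spec, n_regions, years = 19, output_dir = ".") {
  stopifnot(inherits(spec, "synthetic_region_spec"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- generate_region_params(spec, n_regions)
  table_file <- file.path(output_dir, "synthetic_regions.csv")
  write_region_table(params, table_file)
  series_files <- character(0)
  for (i in seq_along(params)) {
    p <- params[[i]]
    obs <- generate_observed_series(p, years = years, cv = spec$cv,
                                    seed = spec$seed + i)
    f <- file.path(output_dir, sprintf("observed_%s.csv", p$region))
    utils::write.csv(obs, f, row.names = FALSE)
    series_files <- c(series_files, f)
  }
  invisible(list(table_file = table_file, series_files = series_files,
                 params = params))
}
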