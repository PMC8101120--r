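#' Region parameter set for the illness-death model
#'
#' Bundles one region's published rates, all expressed per 100,000 per year,
#' together with the prevalent-case count at the start of the projection.
#' Uncertainty-interval (UI) bounds accompany the prevalence ratio and the two
#' death rates; the incidence rate is published as a point value only.
#'
#' @param region Region or country name.
#' @param incidence Incidence rate, new cases per 100,000 person-years among
#'   the healthy population. A single nonnegative number.
#' @param prevalence Prevalence ratio, prevalent cases per 100,000 persons.
#'   Either a single point value or a length-3 vector `(point, ui_low,
#'   ui_high)`.
#' @param ibd_death Death rate due to IBD, per 100,000 total population per
#'   year. Point value or `(point, ui_low, ui_high)`.
#' @param bg_death Death rate due to all other causes acting on the healthy
#'   population, per 100,000 per year. Point value or `(point, ui_low,
#'   ui_high)`.
#' @param initial_cases Prevalent IBD cases (persons) at `start_year`.
#' @param start_year First calendar year of the projection (default 2017).
#'
#' @return An object of class `region_params`: a list with components
#'   `region`, `incidence`, `prevalence`, `ibd_death`, `bg_death` (each UI
#'   field a named vector `point`/`ui_low`/`ui_high`, bounds `NA` when not
#'   supplied), `initial_cases` and `start_year`.
#'
#' @examples
#' iran <- region_params("Iran",
#'   incidence = 3.11, prevalence = c(27.0, 24.6, 29.6),
#'   ibd_death = c(0.16, 0.06, 0.19), bg_death = c(463.97, 452.58, 477.04),
#'   initial_cases = 23812)
#' iran
#' @seealso [load_region_table()], [to_model_rates()], [derive_initial_state()]
#' @export
region_params <- function(region, incidence, prevalence, ibd_death, bg_death,
                          initial_cases, start_year = 2017) {
  stopifnot(is.character(region), length(region) == 1L, nzchar(region))
  p <- structure(list(
    region        = region,
    incidence     = as_point(incidence, region, "incidence"),
    prevalence    = as_ui(prevalence, region, "prevalence"),
    ibd_death     = as_ui(ibd_death, region, "ibd_death"),
    bg_death      = as_ui(bg_death, region, "bg_death"),
    initial_cases = as_point(initial_cases, region, "initial_cases"),
    start_year    = as.numeric(start_year)
  ), class = "region_params")
  validate_region_params(p)
}

as_point <- function(x, region, field) {
  x <- as.numeric(x)
  if (length(x) != 1L || is.na(x))
    stop(sprintf("region '%s': field '%s' must be a single number", region, field),
         call. = FALSE)
  x
}

as_ui <- function(x, region, field) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- c(x, NA_real_, NA_real_)
  if (length(x) != 3L)
    stop(sprintf("region '%s': field '%s' must have 1 or 3 values (point, ui_low, ui_high)",
                 region, field), call. = FALSE)
  names(x) <- c("point", "ui_low", "ui_high")
  x
}

validate_region_params <- function(p) {
  reject <- function(field, msg)
    stop(sprintf("region '%s': %s (field '%s')", p$region, msg, field), call. = FALSE)
  for (field in c("incidence", "initial_cases"))
    if (p[[field]] < 0) reject(field, "negative value")
  if (p$start_year < 0) reject("start_year", "negative value")
  for (field in c("prevalence", "ibd_death", "bg_death")) {
    ui <- p[[field]]
    if (ui[["point"]] < 0 || any(ui < 0, na.rm = TRUE))
      reject(field, "negative rate")
    if (!any(is.na(ui)) &&
        (ui[["ui_low"]] > ui[["point"]] || ui[["point"]] > ui[["ui_high"]]))
      reject(field, "inverted uncertainty interval (need ui_low <= point <= ui_high)")
    if (xor(is.na(ui[["ui_low"]]), is.na(ui[["ui_high"]])))
      reject(field, "one-sided uncertainty interval")
  }
  if (p$initial_cases > 0 && p$prevalence[["point"]] <= 0)
    reject("prevalence", "zero prevalence ratio with nonzero initial cases")
  p
}

#' @export
print.region_params <- function(x, ...) {
  fmt_ui <- function(ui) {
    if (any(is.na(ui))) sprintf("%.4g", ui[["point"]])
    else sprintf("%.4g (%.4g-%.4g)", ui[["point"]], ui[["ui_low"]], ui[["ui_high"]])
  }
  cat(sprintf("Region parameters: %s (start %d)\n", x$region, as.integer(x$start_year)))
  cat(sprintf("  incidence          %.4g per 100,000 person-years\n", x$incidence))
  cat(sprintf("  prevalence ratio   %s per 100,000\n", fmt_ui(x$prevalence)))
  cat(sprintf("  IBD death rate     %s per 100,000/year\n", fmt_ui(x$ibd_death)))
  cat(sprintf("  other-cause deaths %s per 100,000/year\n", fmt_ui(x$bg_death)))
  cat(sprintf("  initial cases      %s persons\n",
              format(x$initial_cases, big.mark = ",")))
  invisible(x)
}

.region_table_cols <- c("region", "incidence", "prev", "prev_lo", "prev_hi",
                        "ibd_death", "ibd_death_lo", "ibd_death_hi",
                        "bg_death", "bg_death_lo", "bg_death_hi",
                        "initial_cases", "start_year")

#' Read a region parameter table from CSV
#'
#' Reads a comma-separated table with one row per region and the columns
#' `region, incidence, prev, prev_lo, prev_hi, ibd_death, ibd_death_lo,
#' ibd_death_hi, bg_death, bg_death_lo, bg_death_hi, initial_cases,
#' start_year`, all rates per 100,000 per year. Every row is validated;
#' invariant violations (negative rates, inverted intervals) are rejected
#' with an error naming the region and field, never silently clamped.
#'
#' @param path Path to the CSV file.
#' @return A named list of [region_params()] objects (names = region), of
#'   class `region_table`. An empty table yields an empty list.
#' @examples
#' tab <- load_region_table(system.file("extdata", "asia_ibd_table1.csv",
#'                                      package = "ibdforecast"))
#' names(tab)
#' @seealso [write_region_table()], [asia_ibd_table()]
#' @export
load_region_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.region_table_cols, names(df))
  if (length(missing))
    stop("region table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    out[[i]] <- region_params(
      region        = r$region,
      incidence     = r$incidence,
      prevalence    = c(r$prev, r$prev_lo, r$prev_hi),
      ibd_death     = c(r$ibd_death, r$ibd_death_lo, r$ibd_death_hi),
      bg_death      = c(r$bg_death, r$bg_death_lo, r$bg_death_hi),
      initial_cases = r$initial_cases,
      start_year    = r$start_year
    )
  }
  names(out) <- vapply(out, `[[`, "", "region")
  structure(out, class = c("region_table", "list"))
}

#' Write a region parameter table to CSV
#'
#' Inverse of [load_region_table()]: values survive the round trip at full
#' double precision (15 significant digits).
#'
#' @param params A list of [region_params()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(params, path) {
  rows <- lapply(params, function(p) {
    data.frame(region = p$region, incidence = p$incidence,
               prev = p$prevalence[["point"]],
               prev_lo = p$prevalence[["ui_low"]],
               prev_hi = p$prevalence[["ui_high"]],
               ibd_death = p$ibd_death[["point"]],
               ibd_death_lo = p$ibd_death[["ui_low"]],
               ibd_death_hi = p$ibd_death[["ui_high"]],
               bg_death = p$bg_death[["point"]],
               bg_death_lo = p$bg_death[["ui_low"]],
               bg_death_hi = p$bg_death[["ui_high"]],
               initial_cases = p$initial_cases,
               start_year = p$start_year,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # 17 significant digits round-trips IEEE doubles exactly
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Published Asian region rate table, 2017 baseline
#'
#' Returns the packaged per-region parameter table for the six Asian
#' regions/countries (Iran, High-income Asia-Pacific, East Asia, Southeast
#' Asia, North Africa and Middle East, South Asia (India)): literature-based
#' incidence, prevalence ratio and death rates with 95% uncertainty
#' intervals, plus the 2017 prevalent-case counts that anchor the
#' projections.
#'
#' @return A `region_table` (named list of [region_params()]).
#' @examples
#' asia_ibd_table()[["Iran"]]
#' @export
asia_ibd_table <- function() {
  load_region_table(system.file("extdata", "asia_ibd_table1.csv",
                                package = "ibdforecast", mustWork = TRUE))
}

#' Compartment state of the illness-death model
#'
#' A population snapshot: calendar year, healthy persons, prevalent IBD
#' cases, and cumulative deaths since the projection start.
#'
#' @param year Calendar time (real-valued for the deterministic model,
#'   integer for the stochastic chain).
#' @param healthy,ibd,dead_cum Nonnegative person counts.
#' @param integer_valued If `TRUE`, require all compartments to be whole
#'   numbers (the stochastic contract).
#' @return An object of class `compartment_state`.
#' @export
compartment_state <- function(year, healthy, ibd, dead_cum = 0,
                              integer_valued = FALSE) {
  s <- list(year = as.numeric(year), healthy = as.numeric(healthy),
            ibd = as.numeric(ibd), dead_cum = as.numeric(dead_cum))
  if (any(vapply(s, length, 1L) != 1L) || anyNA(unlist(s)))
    stop("compartment_state fields must be single non-missing numbers",
         call. = FALSE)
  if (s$healthy < 0 || s$ibd < 0 || s$dead_cum < 0)
    stop("compartment counts must be nonnegative", call. = FALSE)
  if (integer_valued && any(unlist(s[c("healthy", "ibd", "dead_cum")]) %% 1 != 0))
    stop("compartment counts must be integers for stochastic use", call. = FALSE)
  structure(s, class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat(sprintf("Compartment state, year %s: healthy %s | IBD %s | deaths (cum.) %s\n",
              format(x$year),
              format(x$healthy, big.mark = ","),
              format(x$ibd, big.mark = ","),
              format(x$dead_cum, big.mark = ",")))
  invisible(x)
}

#' Derive the initial compartment state from printed prevalence
#'
#' The source publications report prevalent cases and a prevalence ratio but
#' not the population total each projection used. The two printed quantities
#' imply it: `total = initial_cases / prevalence * 100,000`. The healthy pool
#' is the remainder after removing prevalent cases.
#'
#' @param p A [region_params()] object.
#' @param which Which prevalence-ratio component to use for the
#'   back-derivation (`"point"`, `"ui_low"`, `"ui_high"`).
#' @param population Optional explicit total population. Required when
#'   `initial_cases` is zero (a disease-free region carries no information
#'   about its own population size); overrides the back-derivation otherwise.
#' @return A [compartment_state()] at `p$start_year` with `dead_cum = 0`.
#' @examples
#' derive_initial_state(asia_ibd_table()[["Iran"]])  # total ~ 88.19 million
#' @export
derive_initial_state <- function(p, which = "point", population = NULL) {
  stopifnot(inherits(p, "region_params"))
  if (!is.null(population)) {
    if (population < p$initial_cases)
      stop("population smaller than initial prevalent cases", call. = FALSE)
    return(compartment_state(p$start_year, population - p$initial_cases,
                             p$initial_cases))
  }
  if (p$initial_cases == 0)
    stop("initial_cases is zero: the prevalence ratio cannot determine the ",
         "population; supply `population` explicitly", call. = FALSE)
  prev <- ui_component(p$prevalence, which, p$region, "prevalence")
  if (prev <= 0)
    stop(sprintf("region '%s': cannot divide by zero prevalence ratio", p$region),
         call. = FALSE)
  total <- p$initial_cases / prev * 1e5
  compartment_state(p$start_year, total - p$initial_cases, p$initial_cases)
}

ui_component <- function(ui, which, region, field) {
  which <- match.arg(which, c("point", "ui_low", "ui_high"))
  v <- ui[[which]]
  if (is.na(v))
    stop(sprintf("region '%s': '%s' bound requested but no uncertainty interval supplied for '%s'",
                 region, which, field), call. = FALSE)
  v
}

#' Per-capita transition rates of the illness-death model
#'
#' Container for the annual per-capita hazards driving both model engines:
#' `lambda_inc` (incidence hazard on the healthy), `mu_ibd` (mortality hazard
#' per IBD patient), `d_background` (other-cause mortality hazard on the
#' healthy), and the birth inflow closing the demography. Hazards are held
#' constant over the whole projection (the model's stationarity assumption).
#'
#' @param lambda_inc,mu_ibd,d_background Annual per-capita hazards, each in
#'   `[0, 1)`.
#' @param birth_inflow Either a nonnegative number (persons/year) or the
#'   symbolic closure `"stationary-healthy"`, resolved against an initial
#'   state to the inflow that exactly replenishes the healthy pool:
#'   `(d_background + lambda_inc) * healthy(start)`.
#' @return An object of class `model_rates`.
#' @seealso [to_model_rates()], [resolve_birth_inflow()]
#' @export
model_rates <- function(lambda_inc, mu_ibd, d_background,
                        birth_inflow = "stationary-healthy") {
  haz <- c(lambda_inc = lambda_inc, mu_ibd = mu_ibd, d_background = d_background)
  if (anyNA(haz) || any(haz < 0) || any(haz >= 1))
    stop("hazards must lie in [0, 1) per year; got ",
         paste(sprintf("%s=%g", names(haz), haz), collapse = ", "), call. = FALSE)
  symbolic <- identical(birth_inflow, "stationary-healthy")
  if (!symbolic) {
    birth_inflow <- as.numeric(birth_inflow)
    if (length(birth_inflow) != 1L || is.na(birth_inflow) || birth_inflow < 0)
      stop("birth_inflow must be 'stationary-healthy' or a nonnegative number",
           call. = FALSE)
  }
  structure(list(lambda_inc = as.numeric(lambda_inc),
                 mu_ibd = as.numeric(mu_ibd),
                 d_background = as.numeric(d_background),
                 birth_inflow = birth_inflow,
                 closure = if (symbolic) "stationary-healthy" else "constant"),
            class = "model_rates")
}

#' @export
print.model_rates <- function(x, ...) {
  cat("Illness-death model hazards (per person-year):\n")
  cat(sprintf("  incidence (healthy -> IBD)     %.6g\n", x$lambda_inc))
  cat(sprintf("  IBD mortality (per patient)    %.6g\n", x$mu_ibd))
  cat(sprintf("  background mortality (healthy) %.6g\n", x$d_background))
  if (x$closure == "stationary-healthy" && !is.numeric(x$birth_inflow))
    cat("  birth inflow: stationary-healthy closure (unresolved)\n")
  else
    cat(sprintf("  birth inflow: %.6g persons/year [%s closure]\n",
                as.numeric(x$birth_inflow), x$closure))
  invisible(x)
}

#' Convert printed per-100,000 rates to per-capita model hazards
#'
#' `lambda_inc` and `d_background` are direct unit conversions (divide by
#' 100,000). The published IBD death rate is expressed per 100,000 *total*
#' population while the model needs a hazard per *patient*; dividing by the
#' prevalence ratio (same denominator) gives deaths among patients per
#' patient-year: `mu_ibd = ibd_death / prevalence`.
#'
#' @param p A [region_params()] object.
#' @param which Which UI component to take for fields that carry one
#'   (`"point"`, `"ui_low"`, `"ui_high"`). Requesting a bound that was not
#'   supplied is an error.
#' @param birth_inflow Demographic closure passed through to [model_rates()];
#'   default the stationary-healthy closure.
#' @return A [model_rates()] object.
#' @examples
#' to_model_rates(asia_ibd_table()[["Iran"]])
#' @export
to_model_rates <- function(p, which = c("point", "ui_low", "ui_high"),
                           birth_inflow = "stationary-healthy") {
  stopifnot(inherits(p, "region_params"))
  which <- match.arg(which)
  pick <- function(field) ui_component(p[[field]], which, p$region, field)
  prev <- pick("prevalence")
  ibd_death <- pick("ibd_death")
  mu <- if (ibd_death == 0) 0 else {
    if (prev <= 0)
      stop(sprintf("region '%s': prevalence ratio must be positive to form the per-patient IBD mortality hazard",
                   p$region), call. = FALSE)
    ibd_death / prev
  }
  model_rates(lambda_inc = p$incidence / 1e5,
              mu_ibd = mu,
              d_background = pick("bg_death") / 1e5,
              birth_inflow = birth_inflow)
}

#' Resolve a symbolic birth-inflow closure against an initial state
#'
#' Under the `"stationary-healthy"` closure the annual birth inflow equals
#' the healthy pool's annual losses at the start, `(d_background +
#' lambda_inc) * healthy(start)`, so the healthy compartment is exactly
#' replenished and stays constant in the deterministic model.
#'
#' @param rates A [model_rates()] object.
#' @param state0 A [compartment_state()] giving `healthy` at the start.
#' @return `rates` with `birth_inflow` a number.
#' @export
resolve_birth_inflow <- function(rates, state0) {
  stopifnot(inherits(rates, "model_rates"), inherits(state0, "compartment_state"))
  if (is.numeric(rates$birth_inflow)) return(rates)
  rates$birth_inflow <- (rates$d_background + rates$lambda_inc) * state0$healthy
  rates
}
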