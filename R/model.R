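#' Construct an illness-death projection model for one region
#'
#' Binds a region's published rates to the three-state illness-death model
#' (healthy, IBD, dead; no recovery): converts the per-100,000 rates to
#' per-capita hazards, back-derives the starting population from the
#' prevalence ratio and the prevalent-case count, and resolves the
#' demographic closure. The returned object drives both engines: the
#' deterministic ODE via [predict.illness_death()] and the stochastic Markov
#' chain via [simulate.illness_death()].
#'
#' @param params A [region_params()] object.
#' @param which UI component used for the rates (`"point"`, `"ui_low"`,
#'   `"ui_high"`).
#' @param birth_inflow Demographic closure: `"stationary-healthy"` (default;
#'   births exactly replenish the healthy pool) or a constant persons/year.
#' @param population Optional explicit total population, overriding the
#'   back-derivation (see [derive_initial_state()]).
#' @return An object of class `illness_death` with components `params`,
#'   `rates` (resolved [model_rates()]), `state0` ([compartment_state()])
#'   and `which`.
#' @examples
#' m <- illness_death(asia_ibd_table()[["Iran"]])
#' m
#' coef(m)
#' tail(predict(m), 1)
#' @export
illness_death <- function(params, which = "point",
                          birth_inflow = "stationary-healthy",
                          population = NULL) {
  stopifnot(inherits(params, "region_params"))
  state0 <- derive_initial_state(params, which = if (is.null(population)) which
                                                 else "point",
                                 population = population)
  rates <- resolve_birth_inflow(to_model_rates(params, which, birth_inflow),
                                state0)
  structure(list(params = params, rates = rates, state0 = state0, which = which),
            class = "illness_death")
}

#' @export
print.illness_death <- function(x, ...) {
  cat(sprintf("Illness-death model: %s (%s rates, start %d)\n",
              x$params$region, x$which, as.integer(x$state0$year)))
  cat(sprintf("  population %s | healthy %s | prevalent IBD %s\n",
              format(round(x$state0$healthy + x$state0$ibd), big.mark = ","),
              format(round(x$state0$healthy), big.mark = ","),
              format(round(x$state0$ibd), big.mark = ",")))
  print(x$rates)
  invisible(x)
}

#' @export
coef.illness_death <- function(object, ...) {
  c(lambda_inc = object$rates$lambda_inc,
    mu_ibd = object$rates$mu_ibd,
    d_background = object$rates$d_background,
    birth_inflow = object$rates$birth_inflow)
}

#' Deterministic projection of an illness-death model
#'
#' Integrates the ODE engine over the requested horizon; see
#' [project_trajectory()].
#'
#' @param object An [illness_death()] model.
#' @param horizon_years Projection length (default 18, i.e. 2017 to 2035 for
#'   the packaged table).
#' @param output_step Grid spacing in years.
#' @param ... Passed to [project_trajectory()].
#' @return An `ibd_trajectory` data frame.
#' @export
predict.illness_death <- function(object, horizon_years = 18, output_step = 1,
                                  ...) {
  project_trajectory(object$state0, object$rates, horizon_years, output_step,
                     ...)
}

#' Stochastic Monte-Carlo projection of an illness-death model
#'
#' Runs the Markov-chain engine ([simulate_ensemble()]) with annual steps.
#' The initial compartments are rounded to integers (the chain is a
#' finite-population process).
#'
#' @param object An [illness_death()] model.
#' @param nsim Number of replicates (default 200).
#' @param seed Master seed; required for reproducibility, defaults to 1.
#' @param horizon_years Projection length in whole years.
#' @param ... Unused.
#' @return An `ibd_ensemble`; see [simulate_ensemble()].
#' @export
simulate.illness_death <- function(object, nsim = 200, seed = 1,
                                   horizon_years = 18, ...) {
  state0 <- compartment_state(object$state0$year,
                              round(object$state0$healthy),
                              round(object$state0$ibd),
                              round(object$state0$dead_cum),
                              integer_valued = TRUE)
  simulate_ensemble(state0, object$rates, horizon_years = horizon_years,
                    replicates = nsim, master_seed = seed)
}

#' @export
summary.illness_death <- function(object, horizon_years = 18, ...) {
  traj <- predict(object, horizon_years = horizon_years)
  yr0 <- traj$year[1]; yrN <- traj$year[nrow(traj)]
  out <- list(region = object$params$region,
              trajectory = traj,
              doubling_time = doubling_time(traj, yr0),
              fold_change = fold_change(traj, yr0, yrN))
  class(out) <- "summary.illness_death"
  out
}

#' @export
print.summary.illness_death <- function(x, ...) {
  traj <- x$trajectory
  n <- nrow(traj)
  cat(sprintf("Illness-death projection summary: %s\n", x$region))
  cat(sprintf("  %s: %.3f thousand prevalent cases\n",
              format(traj$year[1]), traj$ibd[1] / 1e3))
  cat(sprintf("  %s: %.3f thousand prevalent cases\n",
              format(traj$year[n]), traj$ibd[n] / 1e3))
  cat(sprintf("  fold change: %.2f\n", x$fold_change))
  if (is.finite(x$doubling_time))
    cat(sprintf("  doubling time from %s: %.1f years\n",
                format(traj$year[1]), x$doubling_time))
  else
    cat(sprintf("  doubling not reached within the horizon\n"))
  invisible(x)
}

#' @export
plot.illness_death <- function(x, horizon_years = 18, interval = TRUE, ...) {
  has_ui <- !anyNA(unlist(x$params[c("prevalence", "ibd_death", "bg_death")]))
  if (interval && has_ui) {
    band <- project_interval(x$params, horizon_years)
    graphics::plot(band$year, band$ibd_point / 1e3, type = "n",
                   ylim = range(band$ibd_low, band$ibd_high) / 1e3,
                   xlab = "Year", ylab = "Prevalent IBD cases (thousands)",
                   main = x$params$region, ...)
    graphics::polygon(c(band$year, rev(band$year)),
                      c(band$ibd_low, rev(band$ibd_high)) / 1e3,
                      col = "grey85", border = NA)
    graphics::lines(band$year, band$ibd_point / 1e3, lwd = 2)
  } else {
    traj <- predict(x, horizon_years = horizon_years)
    plot(traj, main = x$params$region, ...)
  }
  invisible(x)
}
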