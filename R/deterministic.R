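#' Right-hand side of the illness-death ODE system
#'
#' The deterministic model is the linear two-compartment system
#' \deqn{dH/dt = -(d + \lambda) H + B}
#' \deqn{dI/dt = \lambda H - \mu I}
#' with \eqn{\lambda} the incidence hazard, \eqn{d} the background mortality
#' hazard on the healthy, \eqn{\mu} the per-patient IBD mortality hazard and
#' \eqn{B} the birth inflow. Deaths are tracked explicitly as
#' \eqn{dD/dt = d H + \mu I} so that person bookkeeping is conserved:
#' \eqn{H + I + D - B t} is constant.
#'
#' @param state A [compartment_state()] (the `year` field is ignored; the
#'   system is autonomous).
#' @param rates A [model_rates()] with a numeric (resolved) `birth_inflow`.
#' @return Named numeric vector `c(dhealthy, dibd, ddead)` in persons/year.
#' @examples
#' r <- model_rates(3.11e-5, 0, 0, birth_inflow = 0)
#' ode_rhs(compartment_state(2017, 1e5, 0), r)  # dibd = 3.11
#' @export
ode_rhs <- function(state, rates) {
  stopifnot(inherits(state, "compartment_state"), inherits(rates, "model_rates"))
  if (!is.numeric(rates$birth_inflow))
    stop("birth_inflow is symbolic; resolve it with resolve_birth_inflow() first",
         call. = FALSE)
  H <- state$healthy; I <- state$ibd
  lam <- rates$lambda_inc; mu <- rates$mu_ibd
  d <- rates$d_background; B <- rates$birth_inflow
  c(dhealthy = -(d + lam) * H + B,
    dibd     = lam * H - mu * I,
    ddead    = d * H + mu * I)
}

#' Integrate the deterministic illness-death model
#'
#' Solves the linear ODE system with an adaptive integrator
#' ([deSolve::ode()], `lsoda`) at tight tolerance and returns the trajectory
#' on the requested annual (or finer) grid. The solution is verified against
#' the person-conservation identity at every grid point; failure to conserve
#' raises an error rather than returning a silent partial trajectory.
#'
#' @param state0 Initial [compartment_state()].
#' @param rates A [model_rates()]; a symbolic closure is resolved against
#'   `state0`.
#' @param horizon_years Projection length in years (> 0).
#' @param output_step Output grid spacing in years (default 1).
#' @param rtol,atol Integrator tolerances.
#' @return An `ibd_trajectory`: a data frame with columns `year`, `healthy`,
#'   `ibd`, `dead_cum` and attributes `rates` and `state0`.
#' @examples
#' m <- illness_death(asia_ibd_table()[["Iran"]])
#' traj <- project_trajectory(m$state0, m$rates, horizon_years = 18)
#' tail(traj, 1)  # about 68,200 prevalent cases in 2035
#' @export
project_trajectory <- function(state0, rates, horizon_years,
                               output_step = 1, rtol = 1e-9, atol = 1e-6) {
  stopifnot(inherits(state0, "compartment_state"), inherits(rates, "model_rates"),
            horizon_years > 0, output_step > 0)
  rates <- resolve_birth_inflow(rates, state0)
  times <- seq(0, horizon_years, by = output_step)
  if (times[length(times)] < horizon_years) times <- c(times, horizon_years)
  y0 <- c(H = state0$healthy, I = state0$ibd, D = state0$dead_cum)
  par <- rates
  rhs <- function(t, y, p)
    list(c(-(p$d_background + p$lambda_inc) * y[1] + p$birth_inflow,
           p$lambda_inc * y[1] - p$mu_ibd * y[2],
           p$d_background * y[1] + p$mu_ibd * y[2]))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = par,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("ODE solver failed to meet the requested tolerance", call. = FALSE)
  out <- as.data.frame(sol)
  if (nrow(out) != length(times) || anyNA(out))
    stop("ODE solver returned an incomplete trajectory", call. = FALSE)
  # conservation check: H + I + D - B*t invariant
  total0 <- state0$healthy + state0$ibd + state0$dead_cum
  drift <- (out$H + out$I + out$D - rates$birth_inflow * out$time) - total0
  if (max(abs(drift)) > 1e-6 * max(total0, 1))
    stop("conservation violated beyond tolerance; integration rejected",
         call. = FALSE)
  traj <- data.frame(year = state0$year + out$time,
                     healthy = out$H, ibd = out$I, dead_cum = out$D)
  structure(traj, class = c("ibd_trajectory", "data.frame"),
            rates = rates, state0 = state0)
}

#' Closed-form prevalent-case count under the stationary-healthy closure
#'
#' When births exactly replenish the healthy pool, `H(t) = H0` and the IBD
#' compartment obeys \eqn{dI/dt = a - \mu I} with \eqn{a = \lambda H_0},
#' whose solution is
#' \deqn{I(t) = a/\mu + (I_0 - a/\mu) e^{-\mu t}} (and \eqn{I_0 + a t} in the
#' nonfatal limit \eqn{\mu = 0}). Used throughout the test suite as the
#' independent oracle for the numerical integrator.
#'
#' @param state0 Initial [compartment_state()].
#' @param rates A [model_rates()] under the `"stationary-healthy"` closure
#'   (calling this with a constant-inflow closure is a contract error).
#' @param t Years since the start; vectorised.
#' @return Prevalent IBD cases (persons) at each `t`.
#' @export
closed_form_prevalence <- function(state0, rates, t) {
  stopifnot(inherits(state0, "compartment_state"), inherits(rates, "model_rates"))
  if (rates$closure != "stationary-healthy")
    stop("closed form requires the stationary-healthy closure", call. = FALSE)
  a <- rates$lambda_inc * state0$healthy
  mu <- rates$mu_ibd
  if (mu == 0) state0$ibd + a * t
  else a / mu + (state0$ibd - a / mu) * exp(-mu * t)
}

#' Project an uncertainty band from published 95% UI bounds
#'
#' Propagates the uncertainty intervals of the prevalence ratio, the IBD
#' death rate and the background death rate through the deterministic model.
#' Because the prevalence ratio enters twice with opposite directions — it
#' sets both the back-derived population (hence the incidence inflow) and
#' the per-patient mortality hazard — no single corner is guaranteed
#' extremal, so all `2^3` corner combinations are integrated and the
#' pointwise envelope taken. The band is conservative by construction and
#' always brackets the point trajectory.
#'
#' @param p A [region_params()] with all UI bounds present.
#' @param horizon_years,output_step Grid, as in [project_trajectory()].
#' @return An `interval_projection`: data frame `year`, `ibd_point`,
#'   `ibd_low`, `ibd_high` (persons), with `ibd_low <= ibd_point <= ibd_high`
#'   at every grid point.
#' @export
project_interval <- function(p, horizon_years, output_step = 1) {
  stopifnot(inherits(p, "region_params"))
  run <- function(prev, ibd_death, bg_death) {
    q <- p
    q$prevalence[] <- prev; q$ibd_death[] <- ibd_death; q$bg_death[] <- bg_death
    st <- derive_initial_state(q)
    project_trajectory(st, to_model_rates(q), horizon_years, output_step)$ibd
  }
  comp <- function(field) {
    ui <- p[[field]]
    if (any(is.na(ui)))
      stop(sprintf("region '%s': uncertainty interval missing for '%s'",
                   p$region, field), call. = FALSE)
    ui
  }
  prev <- comp("prevalence"); ibd <- comp("ibd_death"); bg <- comp("bg_death")
  point <- run(prev[["point"]], ibd[["point"]], bg[["point"]])
  corners <- expand.grid(prev = prev[c("ui_low", "ui_high")],
                         ibd = ibd[c("ui_low", "ui_high")],
                         bg = bg[c("ui_low", "ui_high")])
  runs <- mapply(run, corners$prev, corners$ibd, corners$bg)
  lo <- pmin(apply(runs, 1, min), point)
  hi <- pmax(apply(runs, 1, max), point)
  grid <- p$start_year + seq(0, horizon_years, by = output_step)
  structure(data.frame(year = grid, ibd_point = point, ibd_low = lo, ibd_high = hi),
            class = c("interval_projection", "data.frame"))
}

#' Local sensitivity analysis of the projected IBD count
#'
#' Normalised sensitivity coefficients (elasticities)
#' \eqn{(\partial I(t)/\partial \theta)\,(\theta / I(t))} of the projected
#' prevalent-case count with respect to each model rate, by central finite
#' differences on the full ODE solution with all other parameters (including
#' the resolved birth inflow) held fixed. By model structure the incidence
#' elasticity is nonnegative and the IBD-mortality elasticity nonpositive
#' for all `t > 0`.
#'
#' @param model An [illness_death()] model (or a [region_params()], which is
#'   promoted with defaults).
#' @param t Years since the start at which to evaluate; vectorised.
#' @param rel_perturbation Relative perturbation step (default `1e-3`).
#' @return A `sensitivity_result` data frame: `parameter`, `time`,
#'   `elasticity`.
#' @export
rate_sensitivity <- function(model, t, rel_perturbation = 1e-3) {
  if (inherits(model, "region_params")) model <- illness_death(model)
  stopifnot(inherits(model, "illness_death"),
            rel_perturbation > 0, rel_perturbation < 0.5)
  rates <- resolve_birth_inflow(model$rates, model$state0)
  horizon <- max(t)
  solve_at <- function(r) {
    r$closure <- "constant"  # hold B fixed at its numeric value while perturbing
    tr <- project_trajectory(model$state0, r, horizon_years = horizon,
                             output_step = horizon / max(64, 4 * ceiling(horizon)))
    stats::approx(tr$year - model$state0$year, tr$ibd, xout = t)$y
  }
  base <- solve_at(rates)
  if (any(base == 0))
    stop("projected IBD count is zero; elasticity undefined", call. = FALSE)
  pars <- c("lambda_inc", "mu_ibd", "d_background", "birth_inflow")
  rows <- lapply(pars, function(par) {
    theta <- rates[[par]]
    if (theta == 0)
      return(data.frame(parameter = par, time = t, elasticity = 0))
    up <- rates; up[[par]] <- theta * (1 + rel_perturbation)
    dn <- rates; dn[[par]] <- theta * (1 - rel_perturbation)
    el <- (solve_at(up) - solve_at(dn)) / (2 * rel_perturbation * base)
    data.frame(parameter = par, time = t, elasticity = el)
  })
  structure(do.call(rbind, rows),
            class = c("sensitivity_result", "data.frame"))
}

#' Prevalence doubling time
#'
#' Smallest elapsed time for the prevalent-case count to reach twice its
#' value at a reference year, by linear interpolation between trajectory
#' grid points. Returns `Inf` when doubling is not reached within the
#' trajectory horizon (as the published projections find for Southeast
#' Asia, East Asia and High-income Asia-Pacific).
#'
#' @param traj An `ibd_trajectory` (or any data frame with `year` and `ibd`).
#' @param ref_year Reference calendar year; must lie on the trajectory grid.
#' @return Years to doubling (possibly `Inf`).
#' @examples
#' m <- illness_death(asia_ibd_table()[["Iran"]])
#' doubling_time(predict(m), ref_year = 2020)  # close to 13 years
#' @export
doubling_time <- function(traj, ref_year) {
  i0 <- match(ref_year, traj$year)
  if (is.na(i0)) stop("ref_year is not on the trajectory grid", call. = FALSE)
  base <- traj$ibd[i0]
  if (base <= 0) stop("prevalent count at ref_year must be positive", call. = FALSE)
  target <- 2 * base
  ibd <- traj$ibd[i0:nrow(traj)]
  yrs <- traj$year[i0:nrow(traj)]
  hit <- which(ibd >= target)[1]
  if (is.na(hit)) return(Inf)
  if (hit == 1L) return(0)
  # linear interpolation between the bracketing grid points
  frac <- (target - ibd[hit - 1L]) / (ibd[hit] - ibd[hit - 1L])
  (yrs[hit - 1L] + frac * (yrs[hit] - yrs[hit - 1L])) - ref_year
}

#' Fold change in prevalent cases between two years
#'
#' @param traj An `ibd_trajectory` (or any data frame with `year` and `ibd`).
#' @param y1,y2 Calendar years on the trajectory grid.
#' @return `ibd(y2) / ibd(y1)`.
#' @export
fold_change <- function(traj, y1, y2) {
  i1 <- match(y1, traj$year); i2 <- match(y2, traj$year)
  if (is.na(i1) || is.na(i2))
    stop("both years must lie on the trajectory grid", call. = FALSE)
  if (traj$ibd[i1] <= 0)
    stop("prevalent count at y1 must be positive", call. = FALSE)
  traj$ibd[i2] / traj$ibd[i1]
}

#' @export
print.ibd_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Deterministic illness-death trajectory: %d years (%s-%s)\n",
              n - 1L, format(x$year[1]), format(x$year[n])))
  cat(sprintf("  prevalent IBD cases: %s -> %s\n",
              format(round(x$ibd[1]), big.mark = ","),
              format(round(x$ibd[n]), big.mark = ",")))
  invisible(x)
}

#' @export
plot.ibd_trajectory <- function(x, thousands = TRUE, ...) {
  scale <- if (thousands) 1e-3 else 1
  graphics::plot(x$year, x$ibd * scale, type = "l", lwd = 2,
                 xlab = "Year",
                 ylab = if (thousands) "Prevalent IBD cases (thousands)"
                        else "Prevalent IBD cases", ...)
  invisible(x)
}

#' @export
`[.ibd_trajectory` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}
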