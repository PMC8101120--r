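#' One-step Markov transition matrix of the illness-death chain
#'
#' Builds the 3x3 row-stochastic matrix over states (healthy, ibd, dead) for
#' a time step `dt`. The healthy row treats incidence and background death
#' as competing exponential risks: the probability of leaving is
#' `1 - exp(-(lambda + d) dt)`, apportioned between IBD onset and death by
#' hazard share. The IBD row has survival `exp(-mu dt)`; there is no
#' recovery transition, and the dead state is absorbing.
#'
#' @param rates A [model_rates()] object (birth inflow is not part of the
#'   matrix; births are added separately at each step).
#' @param dt Time step in years (default 1, the annual reporting grid).
#' @return A `markov_matrix`: 3x3 numeric matrix with
#'   `dimnames = list(from, to)` over `c("healthy", "ibd", "dead")`; rows sum
#'   to 1 to within 1e-12.
#' @examples
#' build_transition_matrix(to_model_rates(asia_ibd_table()[["Iran"]]))
#' @export
build_transition_matrix <- function(rates, dt = 1) {
  stopifnot(inherits(rates, "model_rates"), dt > 0)
  lam <- rates$lambda_inc; d <- rates$d_background; mu <- rates$mu_ibd
  x <- lam + d
  leave <- -expm1(-x * dt)                 # 1 - exp(-(lam+d) dt), accurate near 0
  if (x == 0) {
    h <- c(1, 0, 0)
  } else {
    h <- c(exp(-x * dt), lam / x * leave, d / x * leave)
  }
  M <- rbind(healthy = h,
             ibd     = c(0, exp(-mu * dt), -expm1(-mu * dt)),
             dead    = c(0, 0, 1))
  colnames(M) <- rownames(M)
  structure(M, class = c("markov_matrix", "matrix"), dt = dt)
}

#' @export
print.markov_matrix <- function(x, ...) {
  cat(sprintf("One-step illness-death transition matrix (dt = %g year):\n",
              attr(x, "dt")))
  print(unclass(x), digits = 6)
  invisible(x)
}

#' Advance an integer compartment state by one Markov step
#'
#' Allocates the healthy occupants by a single multinomial draw over the
#' healthy row and the IBD occupants over the IBD row, then adds the birth
#' inflow (rounded to an integer) to the healthy compartment. Conservation
#' is exact: out-counts sum to in-counts plus births, replicate by
#' replicate. Uses the current R random-number stream; seed management
#' belongs to [simulate_ensemble()].
#'
#' @param state Integer-valued [compartment_state()].
#' @param M A `markov_matrix` from [build_transition_matrix()].
#' @param births Persons entering the healthy compartment this step (>= 0;
#'   rounded to the nearest integer).
#' @return The next [compartment_state()], one `dt` later.
#' @export
markov_step <- function(state, M, births = 0) {
  stopifnot(inherits(state, "compartment_state"), inherits(M, "markov_matrix"),
            births >= 0)
  counts <- c(state$healthy, state$ibd, state$dead_cum)
  if (any(counts %% 1 != 0))
    stop("stochastic step requires integer compartment counts", call. = FALSE)
  from_h <- if (state$healthy > 0)
    as.numeric(stats::rmultinom(1, state$healthy, M["healthy", ])) else c(0, 0, 0)
  from_i <- if (state$ibd > 0)
    as.numeric(stats::rmultinom(1, state$ibd, M["ibd", ])) else c(0, 0, 0)
  compartment_state(state$year + attr(M, "dt"),
                    healthy  = from_h[1] + from_i[1] + round(births),
                    ibd      = from_h[2] + from_i[2],
                    dead_cum = state$dead_cum + from_h[3] + from_i[3],
                    integer_valued = TRUE)
}

#' Monte-Carlo ensemble of the stochastic illness-death chain
#'
#' Simulates `replicates` independent realisations of the annual Markov
#' chain. Each replicate runs on its own substream seeded from the master
#' seed, so a given `master_seed` reproduces the ensemble bit-for-bit and
#' replicates are mutually independent.
#'
#' @param state0 Integer-valued initial [compartment_state()].
#' @param rates A [model_rates()]; a symbolic closure is resolved against
#'   `state0`.
#' @param horizon_years Whole number of annual steps (>= 1).
#' @param replicates Number of replicates (>= 1; default 200).
#' @param master_seed Integer master seed.
#' @return An `ibd_ensemble`: list with `years` (integer grid of length
#'   `horizon_years + 1`), arrays `healthy`, `ibd`, `dead_cum` of dimension
#'   `replicates x length(years)`, the `rates` used, `master_seed` and the
#'   derived per-replicate `substream_seeds`.
#' @examples
#' m <- illness_death(asia_ibd_table()[["Iran"]])
#' ens <- simulate(m, nsim = 50, seed = 7)
#' summarize_ensemble(ens)[c(1, 19), ]
#' @export
simulate_ensemble <- function(state0, rates, horizon_years, replicates = 200,
                              master_seed = 1) {
  stopifnot(inherits(state0, "compartment_state"), inherits(rates, "model_rates"),
            horizon_years >= 1, horizon_years %% 1 == 0, replicates >= 1)
  if (any(c(state0$healthy, state0$ibd, state0$dead_cum) %% 1 != 0))
    stop("stochastic simulation requires integer initial counts", call. = FALSE)
  rates <- resolve_birth_inflow(rates, state0)
  M <- build_transition_matrix(rates, dt = 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, replicates)
  nt <- horizon_years + 1L
  H <- I <- D <- matrix(NA_real_, nrow = replicates, ncol = nt)
  for (r in seq_len(replicates)) {
    set.seed(subseeds[r])
    s <- state0
    H[r, 1] <- s$healthy; I[r, 1] <- s$ibd; D[r, 1] <- s$dead_cum
    for (k in seq_len(horizon_years)) {
      s <- markov_step(s, M, births = rates$birth_inflow)
      H[r, k + 1L] <- s$healthy; I[r, k + 1L] <- s$ibd; D[r, k + 1L] <- s$dead_cum
    }
  }
  structure(list(years = state0$year + 0:horizon_years,
                 healthy = H, ibd = I, dead_cum = D,
                 rates = rates, master_seed = as.integer(master_seed),
                 substream_seeds = subseeds),
            class = "ibd_ensemble")
}

#' @export
print.ibd_ensemble <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf("Stochastic illness-death ensemble: %d replicates, %s-%s (seed %d)\n",
              nrow(x$ibd), format(x$years[1]), format(x$years[n]), x$master_seed))
  cat(sprintf("  mean prevalent IBD cases at %s: %s\n", format(x$years[n]),
              format(round(mean(x$ibd[, n])), big.mark = ",")))
  invisible(x)
}

#' Per-year summaries of a stochastic ensemble
#'
#' @param e An `ibd_ensemble`.
#' @param quantiles Fractions in (0, 1) for empirical quantile columns
#'   (default 2.5% and 97.5%); may be empty for a mean-only table.
#' @return Data frame with `year`, `mean` and one `q<level>` column per
#'   requested quantile of the prevalent IBD count.
#' @export
summarize_ensemble <- function(e, quantiles = c(0.025, 0.975)) {
  stopifnot(inherits(e, "ibd_ensemble"))
  if (length(quantiles) && (any(quantiles <= 0) || any(quantiles >= 1)))
    stop("quantiles must lie strictly between 0 and 1", call. = FALSE)
  out <- data.frame(year = e$years, mean = colMeans(e$ibd))
  for (q in quantiles)
    out[[sprintf("q%g", 100 * q)]] <- apply(e$ibd, 2, stats::quantile,
                                            probs = q, names = FALSE)
  out
}

#' Expected trajectory of the discrete-time chain
#'
#' The exact expectation of the annual Markov update (including the
#' deterministically rounded birth inflow): the mean-field recursion the
#' ensemble mean converges to as replicates grow. Used to check mean-field
#' agreement and to quantify the discretisation gap against the continuous
#' ODE.
#'
#' @param state0 Initial [compartment_state()].
#' @param rates A [model_rates()].
#' @param horizon_years Whole number of annual steps.
#' @return Data frame `year`, `healthy`, `ibd`, `dead_cum` (real-valued).
#' @export
expected_chain <- function(state0, rates, horizon_years) {
  stopifnot(inherits(state0, "compartment_state"), inherits(rates, "model_rates"))
  rates <- resolve_birth_inflow(rates, state0)
  M <- build_transition_matrix(rates, dt = 1)
  B <- round(rates$birth_inflow)
  v <- c(state0$healthy, state0$ibd, state0$dead_cum)
  out <- matrix(NA_real_, nrow = horizon_years + 1L, ncol = 3)
  out[1, ] <- v
  for (k in seq_len(horizon_years)) {
    v <- as.numeric(v %*% unclass(M))
    v[1] <- v[1] + B
    out[k + 1L, ] <- v
  }
  data.frame(year = state0$year + 0:horizon_years,
             healthy = out[, 1], ibd = out[, 2], dead_cum = out[, 3])
}
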