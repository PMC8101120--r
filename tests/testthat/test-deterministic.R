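test_that("the ODE right-hand side reproduces hand-computed flows", {
  # incidence alone: 100,000 healthy at 3.11 per 100,000 -> 3.11 new cases/yr
  r <- model_rates(3.11e-5, 0, 0, birth_inflow = 0)
  d <- ode_rhs(compartment_state(2017, 1e5, 0), r)
  expect_equal(unname(d), c(-3.11, 3.11, 0))
  # births only
  rb <- model_rates(0, 0, 0, birth_inflow = 7)
  expect_equal(unname(ode_rhs(compartment_state(2017, 50, 10), rb)), c(7, 0, 0))
  # symbolic closure must be resolved before evaluating
  expect_error(ode_rhs(compartment_state(2017, 1, 1), model_rates(0.1, 0.1, 0.1)),
               "symbolic")
})

test_that("numerical integration matches the closed-form oracle", {
  for (p in asia_ibd_table()) {
    m <- illness_death(p)
    traj <- predict(m, horizon_years = 18)
    oracle <- closed_form_prevalence(m$state0, m$rates, traj$year - p$start_year)
    expect_lt(max(abs(traj$ibd - oracle) / oracle), 1e-6)
  }
})

test_that("analytic limiting cases are reproduced", {
  # no incidence: pure exponential decay of the prevalent pool
  pd <- region_params("decay", 0, 50, 5, 500, 5000)
  md <- illness_death(pd)
  tr <- predict(md, horizon_years = 10)
  expect_equal(tr$ibd, 5000 * exp(-(5 / 50) * (0:10)), tolerance = 1e-8)
  # nonfatal disease under stationarity: exactly linear growth
  pl <- region_params("linear", 10, 50, 0, 500, 5000)
  ml <- illness_death(pl)
  trl <- predict(ml, horizon_years = 10)
  a <- ml$rates$lambda_inc * ml$state0$healthy
  expect_equal(trl$ibd, 5000 + a * (0:10), tolerance = 1e-8)
})

test_that("persons are conserved along the trajectory", {
  for (p in asia_ibd_table()[c("Iran", "East Asia")]) {
    m <- illness_death(p)
    traj <- predict(m, horizon_years = 18)
    total0 <- m$state0$healthy + m$state0$ibd
    elapsed <- traj$year - p$start_year
    drift <- traj$healthy + traj$ibd + traj$dead_cum -
      m$rates$birth_inflow * elapsed - total0
    expect_lt(max(abs(drift)) / total0, 1e-8)
  }
})

test_that("below-equilibrium trajectories rise monotonically and concavely", {
  m <- illness_death(iran_params())
  traj <- predict(m, horizon_years = 18)
  eq <- m$rates$lambda_inc * m$state0$healthy / m$rates$mu_ibd
  expect_true(all(diff(traj$ibd) > 0))
  expect_true(all(diff(diff(traj$ibd)) < 0))
  expect_true(all(traj$ibd < eq))
})

test_that("the solution is grid-independent up to interpolation", {
  m <- illness_death(iran_params())
  coarse <- predict(m, horizon_years = 18, output_step = 1)
  fine <- predict(m, horizon_years = 18, output_step = 0.5)
  shared <- match(coarse$year, fine$year)
  expect_equal(coarse$ibd, fine$ibd[shared], tolerance = 1e-9)
})

test_that("the UI envelope brackets the point projection", {
  band <- project_interval(iran_params(), horizon_years = 18)
  expect_true(all(band$ibd_low <= band$ibd_point + 1e-9))
  expect_true(all(band$ibd_point <= band$ibd_high + 1e-9))
  # shared initial condition: the band collapses at the start year
  expect_equal(band$ibd_low[1], band$ibd_point[1])
  expect_equal(band$ibd_high[1], band$ibd_point[1])
  # non-degenerate UIs separate strictly by the horizon
  n <- nrow(band)
  expect_lt(band$ibd_low[n], band$ibd_point[n])
  expect_gt(band$ibd_high[n], band$ibd_point[n])
  # degenerate UIs give a zero-width band
  pdeg <- region_params("deg", 3, c(27, 27, 27), c(0.16, 0.16, 0.16),
                        c(464, 464, 464), 1000)
  bdeg <- project_interval(pdeg, horizon_years = 5)
  expect_equal(bdeg$ibd_low, bdeg$ibd_point)
  expect_equal(bdeg$ibd_high, bdeg$ibd_point)
  # missing UI is an error
  pno <- region_params("noui", 3, 27, 0.16, 464, 1000)
  expect_error(project_interval(pno, 5), "missing")
})

test_that("sensitivity elasticities have the structural signs and magnitudes", {
  s <- rate_sensitivity(iran_params(), t = c(5, 18))
  el <- function(par, tt) s$elasticity[s$parameter == par & s$time == tt]
  for (tt in c(5, 18)) {
    expect_gt(el("lambda_inc", tt), 0)
    expect_lt(el("mu_ibd", tt), 0)
  }
  # frozen against a central difference on the closed form: at 18 years the
  # initial cohort still carries ~31% of the prevalent pool, so the
  # incidence elasticity sits near 0.686, well short of 1
  expect_equal(el("lambda_inc", 18), 0.68607, tolerance = 1e-3)
  # central differences are second-order: halving the step barely moves it
  s2 <- rate_sensitivity(iran_params(), t = 18, rel_perturbation = 5e-4)
  expect_equal(s2$elasticity[s2$parameter == "lambda_inc"],
               el("lambda_inc", 18), tolerance = 1e-5)
})

test_that("doubling time interpolates linearly and handles non-doubling", {
  # constructed trajectory doubling exactly mid-interval: 100, 150, 250
  traj <- data.frame(year = 2017:2019, ibd = c(100, 150, 250))
  expect_equal(doubling_time(traj, 2017), 1 + 50 / 100)
  # equilibrium: lambda*H0 = mu*I0 keeps prevalence flat, doubling never comes
  st <- compartment_state(2017, healthy = 1e5, ibd = 1e-4 * 1e5 / 0.1)
  treq <- project_trajectory(st, model_rates(1e-4, 0.1, 5e-3),
                             horizon_years = 18)
  expect_equal(max(abs(treq$ibd - treq$ibd[1])) / treq$ibd[1], 0,
               tolerance = 1e-6)
  expect_identical(doubling_time(treq, 2017), Inf)
  expect_error(doubling_time(traj, 2016), "not on the trajectory grid")
})

test_that("fold change is a plain ratio with guarded degenerate input", {
  m <- illness_death(iran_params())
  traj <- predict(m, horizon_years = 18)
  expect_equal(fold_change(traj, 2020, 2020), 1.0)
  expect_equal(fold_change(traj, 2020, 2035),
               traj$ibd[traj$year == 2035] / traj$ibd[traj$year == 2020])
  expect_gte(fold_change(traj, 2017, 2035), 1)
  z <- data.frame(year = 1:2, ibd = c(0, 5))
  expect_error(fold_change(z, 1, 2), "positive")
})
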