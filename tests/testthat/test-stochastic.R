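test_that("the one-step transition matrix is a proper illness-death kernel", {
  M <- build_transition_matrix(to_model_rates(iran_params()))
  expect_equal(unname(rowSums(M)), c(1, 1, 1), tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
  expect_equal(unname(M["dead", ]), c(0, 0, 1))     # absorbing death
  expect_equal(M["ibd", "healthy"], 0)              # no recovery
  # competing-risks conversion, hand-derived for the Iran rates at dt = 1:
  # lam = 3.11e-5, d = 4.6397e-3 -> p(h->ibd) = lam/(lam+d)*(1-exp(-(lam+d)))
  expect_equal(M["healthy", "ibd"], 3.102748e-5, tolerance = 1e-6)
  expect_equal(M["healthy", "dead"], 4.628881e-3, tolerance = 1e-6)
  expect_equal(M["healthy", "healthy"], exp(-4.6708e-3), tolerance = 1e-7)
})

test_that("transition-matrix limits behave", {
  # no events: identity
  M0 <- build_transition_matrix(model_rates(0, 0, 0, birth_inflow = 0))
  expect_equal(unclass(M0), diag(3), ignore_attr = TRUE)
  # near-certain death of patients
  Md <- build_transition_matrix(model_rates(0, 0.999, 0, birth_inflow = 0),
                                dt = 20)
  expect_gt(Md["ibd", "dead"], 1 - 1e-8)
  # probabilities stay in [0,1] even for aggressive rates and steps
  Mx <- build_transition_matrix(model_rates(0.5, 0.9, 0.4, birth_inflow = 0),
                                dt = 10)
  expect_true(all(Mx >= 0 & Mx <= 1))
  expect_equal(unname(rowSums(Mx)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("a Markov step conserves persons exactly and respects contracts", {
  M <- build_transition_matrix(to_model_rates(toy_params()))
  set.seed(42)
  for (i in 1:20) {
    s <- compartment_state(2017, sample(0:5000, 1), sample(0:500, 1),
                           sample(0:100, 1), integer_valued = TRUE)
    b <- sample(0:50, 1)
    s2 <- markov_step(s, M, births = b)
    expect_identical(s2$healthy + s2$ibd + s2$dead_cum,
                     s$healthy + s$ibd + s$dead_cum + b)
    expect_true(all(c(s2$healthy, s2$ibd, s2$dead_cum) %% 1 == 0))
    expect_gte(s2$dead_cum, s$dead_cum)
  }
  # identity matrix: nothing moves
  Mi <- build_transition_matrix(model_rates(0, 0, 0, birth_inflow = 0))
  s <- compartment_state(2017, 100, 10, 3, integer_valued = TRUE)
  set.seed(1)
  expect_equal(unlist(markov_step(s, Mi, 0)[c("healthy", "ibd", "dead_cum")]),
               c(healthy = 100, ibd = 10, dead_cum = 3))
  # births land in healthy even from an empty population
  s0 <- compartment_state(2017, 0, 0, 5, integer_valued = TRUE)
  s1 <- markov_step(s0, Mi, births = 9)
  expect_equal(unlist(s1[c("healthy", "ibd", "dead_cum")]),
               c(healthy = 9, ibd = 0, dead_cum = 5))
  expect_error(markov_step(compartment_state(2017, 1.5, 0), Mi, 0), "integer")
})

test_that("step expectations match the matrix expectation", {
  p <- toy_params()
  r <- to_model_rates(p)
  M <- build_transition_matrix(r)
  s <- compartment_state(2017, 80000, 400, 0, integer_valued = TRUE)
  set.seed(99)
  draws <- replicate(3000, markov_step(s, M, 0)$ibd)
  expected <- s$healthy * M["healthy", "ibd"] + s$ibd * M["ibd", "ibd"]
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 4 * se)
})

test_that("ensembles are reproducible and respect their invariants", {
  m <- illness_death(toy_params())
  e1 <- simulate(m, nsim = 30, seed = 5, horizon_years = 10)
  e2 <- simulate(m, nsim = 30, seed = 5, horizon_years = 10)
  expect_identical(e1$ibd, e2$ibd)
  expect_identical(e1$healthy, e2$healthy)
  e3 <- simulate(m, nsim = 30, seed = 6, horizon_years = 10)
  expect_false(identical(e1$ibd, e3$ibd))
  # nonnegative integer counts, nondecreasing cumulative deaths
  expect_true(all(e1$ibd >= 0 & e1$ibd %% 1 == 0))
  expect_true(all(e1$healthy >= 0 & e1$healthy %% 1 == 0))
  expect_true(all(apply(e1$dead_cum, 1, function(v) all(diff(v) >= 0))))
  # exact per-replicate conservation including the rounded birth inflow
  births <- round(e1$rates$birth_inflow)
  total <- e1$healthy + e1$ibd + e1$dead_cum
  for (r in 1:nrow(total))
    expect_equal(total[r, ], total[r, 1] + births * (0:10))
})

test_that("an all-zero-rate chain is constant", {
  st <- compartment_state(2017, 1000, 50, 0, integer_valued = TRUE)
  e <- simulate_ensemble(st, model_rates(0, 0, 0, birth_inflow = 0),
                         horizon_years = 5, replicates = 1, master_seed = 3)
  expect_true(all(e$ibd == 50) && all(e$healthy == 1000))
})

test_that("the ensemble mean tracks the discrete-time expectation", {
  m <- illness_death(iran_params())
  e <- simulate(m, nsim = 200, seed = 17)
  ec <- expected_chain(m$state0, m$rates, 18)
  i_final <- e$ibd[, 19]
  se <- sd(i_final) / sqrt(length(i_final))
  expect_lt(abs(mean(i_final) - ec$ibd[19]), 3 * se)
  # and the discrete chain sits within 2% of the continuous ODE at 18 years
  cf <- closed_form_prevalence(m$state0, m$rates, 18)
  expect_lt(abs(ec$ibd[19] - cf) / cf, 0.02)
})

test_that("ensemble variance scales like multinomial demographic noise", {
  # one annual step from a 1e5 population: var(I1) is the sum of the two
  # binomial contributions H*p(1-p) and I*q(1-q)
  p <- toy_params(pop = 1e5)
  m <- illness_death(p)
  M <- build_transition_matrix(m$rates)
  e <- simulate(m, nsim = 600, seed = 21, horizon_years = 1)
  i1 <- e$ibd[, 2]
  H0 <- m$state0$healthy; I0 <- m$state0$ibd
  v_theory <- H0 * M["healthy", "ibd"] * (1 - M["healthy", "ibd"]) +
    I0 * M["ibd", "ibd"] * (1 - M["ibd", "ibd"])
  # chi-square 99% band for a variance ratio with ~600 replicates
  expect_gt(var(i1) / v_theory, 0.8)
  expect_lt(var(i1) / v_theory, 1.25)
})

test_that("ensemble summaries are well-formed", {
  m <- illness_death(toy_params())
  e <- simulate(m, nsim = 25, seed = 2, horizon_years = 6)
  sm <- summarize_ensemble(e, quantiles = c(0.1, 0.5, 0.9))
  expect_named(sm, c("year", "mean", "q10", "q50", "q90"))
  expect_true(all(sm$mean >= apply(e$ibd, 2, min) - 1e-9))
  expect_true(all(sm$mean <= apply(e$ibd, 2, max) + 1e-9))
  # a single replicate is its own mean
  e1 <- simulate(m, nsim = 1, seed = 2, horizon_years = 6)
  sm1 <- summarize_ensemble(e1, quantiles = numeric(0))
  expect_named(sm1, c("year", "mean"))
  expect_equal(sm1$mean, as.numeric(e1$ibd[1, ]))
  expect_error(summarize_ensemble(e, quantiles = c(0, 0.5)), "between 0 and 1")
})
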