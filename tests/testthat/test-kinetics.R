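test_that("activation probability follows the delayed-exponential closed form", {
  expect_equal(activation_probability(kp_es401_fit, 1.0), 0.10)
  expect_equal(activation_probability(kp_es401_fit, 0), 0.10)
  # no switching when the rate is zero
  flat <- kinetic_params(p0 = 0.3, tau_plus = 0.5, lambda_plus = 0)
  expect_equal(activation_probability(flat, c(0, 1, 10, 100)), rep(0.3, 4))
  # saturation limit with instantaneous switching
  inst <- kinetic_params(p0 = 0, tau_plus = 0, lambda_plus = Inf)
  expect_equal(activation_probability(inst, c(0.1, 5)), c(1, 1))
  # agreement with an independently written closed form on a grid
  ts <- seq(0, 6, by = 0.1)
  expect_equal(activation_probability(kp_fqa002_fit, ts),
               eq2_oracle(0.05, 1, 0.05, ts))
  expect_error(activation_probability(kp_es401_fit, -0.1), "negative")
})

test_that("activation probability is monotone, bounded and saturating", {
  for (p in list(kp_es401_fit, kp_fqa002_fit,
                 kinetic_params(0, 2, 1.5), kinetic_params(0.5, 0, 0.2))) {
    ts <- seq(0, 40, by = 0.05)
    v <- activation_probability(p, ts)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= p$p0 - 1e-12 & v <= 1))
    expect_equal(v[ts < p$tau_plus], rep(p$p0, sum(ts < p$tau_plus)))
    if (p$lambda_plus > 0)
      expect_equal(activation_probability(p, 1e4), 1, tolerance = 1e-8)
  }
})

test_that("tau-leap activation stepper matches the closed form in ensemble", {
  set.seed(42)
  n <- 1e5
  st <- reactor_state(n, kp_es401_fit)
  dt <- 0.05
  checks <- c(1, 2, 3, 5)
  for (tt in checks) {
    while (st$t < tt - 1e-9) st <- step_activation(st, kp_es401_fit, dt)
    p <- activation_probability(kp_es401_fit, tt)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(st$G) - p), 4 * se)
  }
  # never switches before the waiting period
  set.seed(1)
  st <- reactor_state(1e4, kinetic_params(0, 1, 50))
  st <- step_activation(st, kinetic_params(0, 1, 50), 0.001)
  expect_equal(sum(st$G), 0)
  # lambda_plus = 0 stays inactive forever
  st <- reactor_state(100, kinetic_params(0, 0, 0))
  for (i in 1:50) st <- step_activation(st, kinetic_params(0, 0, 0), 0.1)
  expect_equal(sum(st$G), 0)
  expect_error(step_activation(st, kinetic_params(0, 0, 5), 0.1), "tau-leap")
})

test_that("sheath stepper conserves counts and respects its preconditions", {
  st <- structure(list(G = rep(TRUE, 5), N = rep(5L, 5), t = 0),
                  class = "t6_reactors")
  out <- step_sheath_dynamics(st, kinetic_params(1, 0, 0, 0, 0), 0.01)
  expect_equal(out$state$N, rep(5L, 5))   # no reactions, no change
  expect_equal(out$fired, rep(0L, 5))
  stbad <- st; stbad$N[2] <- -1L
  expect_error(step_sheath_dynamics(stbad, kp_sheath, 0.001), "negative")
  expect_error(step_sheath_dynamics(st, kp_sheath, 0.05), "reduce dt")
  # inactive reactors hold N fixed
  stg <- structure(list(G = c(TRUE, FALSE), N = c(0L, 3L), t = 0),
                   class = "t6_reactors")
  set.seed(9)
  for (i in 1:200) stg <- step_sheath_dynamics(stg, kp_sheath, 0.004)$state
  expect_equal(stg$N[2], 3L)
})

test_that("tau-leap sheath ensemble approaches the steady-state mean 3.5", {
  set.seed(7)
  n <- 1e4
  st <- structure(list(G = rep(TRUE, n), N = integer(n), t = 0),
                  class = "t6_reactors")
  dt <- 0.002
  for (i in seq_len(round(10 / dt)))
    st <- step_sheath_dynamics(st, kp_sheath, dt)$state
  se <- sd(st$N) / sqrt(n)
  expect_lt(abs(mean(st$N) - 3.5), 3 * se)
  # and the distribution is consistent with the master-equation solution
  pmf <- transient_pmf(kp_sheath, 10)
  k <- length(pmf) - 1
  obs <- tabulate(pmin(st$N, k) + 1L, nbins = k + 1)
  expected <- n * pmf
  keep <- expected > 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi2, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("steady-state mean is lambda_s / lambda_f", {
  expect_equal(steady_state_mean(kinetic_params(0, 0, 0, 21, 6)), 3.5)
  expect_equal(steady_state_mean(kinetic_params(0, 0, 0, 0, 1)), 0)
  expect_equal(steady_state_mean(kinetic_params(0, 0, 0, 20, 20)), 1)
  expect_error(steady_state_mean(kinetic_params(0, 0, 0, 5, 0)),
               "steady state")
})

test_that("master equation conserves probability and matches closed forms", {
  # point mass at zero when nothing has happened
  p <- transient_pmf(kinetic_params(0, 0, 0.5, 21, 6), 0)
  expect_equal(p[1], 1)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  # immigration-death mean from an all-active, empty start
  for (tt in c(0.1, 0.5, 1, 3)) {
    p <- transient_pmf(kp_sheath, tt)
    expect_equal(sum(p), 1, tolerance = 1e-8)
    m <- sum((seq_along(p) - 1) * p)
    expect_equal(m, 3.5 * (1 - exp(-6 * tt)), tolerance = 1e-6)
  }
  # long-time limit is Poisson(lambda_s / lambda_f) in total variation
  p <- transient_pmf(kp_sheath, 12)
  pois <- dpois(seq_along(p) - 1, 3.5)
  expect_lt(0.5 * sum(abs(p - pois)), 1e-6)
  # truncation too tight is flagged
  expect_error(transient_pmf(kp_sheath, 10, n_max = 4), "truncation|n_max")
})

test_that("master equation tracks the two-stage process with delayed activation", {
  # unprimed population: activated fraction must match the closed form
  kp <- kinetic_params(p0 = 0.1, tau_plus = 1, lambda_plus = 0.6,
                       lambda_s = 21, lambda_f = 6)
  set.seed(11)
  sim <- ssa_ensemble(2e4, kp, 3)
  pmf <- transient_pmf(kp, 3)
  k <- length(pmf) - 1
  obs <- tabulate(pmin(sim$N, k) + 1L, nbins = k + 1)
  expected <- 2e4 * pmf
  keep <- expected > 5
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi2, sum(keep) - 1, lower.tail = FALSE), 0.001)
  expect_lt(abs(mean(sim$G) - activation_probability(kp, 3)),
            4 * sqrt(0.25 / 2e4))
})

test_that("exact SSA ensemble agrees with the tau-leap stepper", {
  set.seed(5)
  n <- 2e4
  sim <- ssa_ensemble(n, kp_es401_fit, 3)
  p <- activation_probability(kp_es401_fit, 3)
  expect_lt(abs(mean(sim$G) - p), 4 * sqrt(p * (1 - p) / n))
  # steady-state draw at seeding
  set.seed(6)
  sim2 <- ssa_ensemble(5e3, kp_sheath, 0, init_n = "steady")
  expect_lt(abs(mean(sim2$N) - 3.5), 4 * sqrt(3.5 / 5e3))
})
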