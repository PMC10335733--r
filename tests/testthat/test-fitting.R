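test_that("activation-curve fit recovers exact parameters from noiseless data", {
  ts <- seq(0.5, 3, by = 0.5)
  series <- data.frame(time_h = ts,
                       fraction = eq2_oracle(0.10, 1.34, 0.118, ts))
  fit <- fit_activation_curve(series)
  expect_equal(fit$p0, 0.10, tolerance = 1e-6)
  expect_lt(abs(fit$tau_plus - 1.34), 1e-4)
  expect_lt(abs(fit$lambda_plus - 0.118), 1e-4)
  expect_lt(fit$ssr, 1e-10)
  # and for the slower strain's triple
  series2 <- data.frame(time_h = ts,
                        fraction = eq2_oracle(0.05, 1, 0.05, ts))
  fit2 <- fit_activation_curve(series2)
  expect_lt(abs(fit2$tau_plus - 1), 1e-4)
  expect_lt(abs(fit2$lambda_plus - 0.05), 1e-4)
})

test_that("flat series gives p0 with a vanishing activation rate", {
  series <- data.frame(time_h = seq(0.5, 3, 0.5), fraction = rep(0.10, 6))
  fit <- fit_activation_curve(series)
  expect_equal(fit$p0, 0.10)
  expect_lt(fit$lambda_plus * (1 - exp(-3)), 0.02)  # flat within the window
})

test_that("fit input validation", {
  expect_error(fit_activation_curve(
    data.frame(time_h = 1:3, fraction = c(0.1, 0.2, 0.3))), "4 time points")
  expect_error(fit_activation_curve(
    data.frame(time_h = 1:4, fraction = c(0.1, 0.2, 1.3, 0.4))), "\\[0, 1\\]")
  expect_error(fit_activation_curve(
    data.frame(time_h = c(1, 1, 2, 3), fraction = rep(0.1, 4))),
    "strictly increasing")
})

test_that("fit recovers the activation rate under counting noise", {
  # binomial observation noise at the census size of the assays (680 cells)
  set.seed(2024)
  truth <- kinetic_params(p0 = 0.10, tau_plus = 1.34, lambda_plus = 0.118)
  ts <- seq(0.5, 3, by = 0.5)
  lam_hat <- replicate(200, {
    series <- make_activation_series(truth, ts, n_cells = 680)
    fit_activation_curve(series)$lambda_plus
  })
  expect_lt(abs(median(lam_hat) - 0.118) / 0.118, 0.20)
})

test_that("exponential-decay fit recovers rate and respects the window", {
  ts <- 2:5
  fit <- fit_exponential_decay(ts, 100 * exp(-1.6 * ts))
  expect_lt(abs(fit$b - 1.6), 1e-6)
  expect_lt(abs(fit$a - 100), 1e-4)
  # early points are excluded, so adding them must not change the fit
  fit2 <- fit_exponential_decay(c(0, 1, ts), c(500, 400, 100 * exp(-1.6 * ts)))
  expect_equal(fit2$b, fit$b)
  expect_equal(fit2$a, fit$a)
  # constant counts decay at rate ~0
  flat <- fit_exponential_decay(2:6, rep(40, 5))
  expect_lt(abs(flat$b), 1e-12)
  expect_error(fit_exponential_decay(2:5, c(3, 2, 0, 1)), "positive")
  expect_error(fit_exponential_decay(c(0, 1, 2), c(5, 4, 3)), "at least 2")
})
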