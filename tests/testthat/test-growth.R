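# Closed-form growth law and its set-point consequences.

gp1 <- growth_params(tlag = 0.11 + 0.160, mu_max = 2.14, nu = -0.922)

test_that("published run endpoints are reproduced by the growth law", {
  # run 1: final concentration at tF from the printed best-fit kinetics
  expect_equal(cell_concentration(gp1, 1.49, 5.05), 19.0, tolerance = 0.005)
  # growth starts at tlag
  expect_identical(cell_concentration(gp1, 1.49, gp1$tlag), 1.49)
  expect_identical(cell_concentration(gp1, 1.49, gp1$tlag - 0.1), 1.49)
  # run 5 is the exponential (nu = 0) limit
  gp5 <- growth_params(tlag = 1.92, mu_max = 0.4065, nu = 0)
  expect_equal(cell_concentration(gp5, 1.13, 6.95), 8.73, tolerance = 0.001)
})

test_that("specific growth rate starts at mu_max and declines as specified", {
  expect_identical(specific_growth_rate(gp1, gp1$tlag), 2.14)
  expect_equal(specific_growth_rate(gp1, 5.05),
               2.14 / (1 + 2.14 * 0.922 * (5.05 - 0.27)), tolerance = 1e-12)
  expect_equal(specific_growth_rate(gp1, 5.05), 0.205, tolerance = 0.005)
  gp0 <- growth_params(tlag = 1, mu_max = 0.7, nu = 0)
  expect_equal(specific_growth_rate(gp0, c(1, 3, 10)), rep(0.7, 3))
  expect_identical(specific_growth_rate(gp1, gp1$tlag - 1e-9), 0)
})

test_that("endpoint constraint reproduces the printed growth rates", {
  expect_equal(mu_max_from_endpoint(1.49, 19.0, 0.270, -0.922, 5.05), 2.14,
               tolerance = 0.01)
  # printed inputs are themselves rounded; the formula gives 0.4065
  expect_equal(mu_max_from_endpoint(1.13, 8.73, 1.92, 0, 6.95), 0.405,
               tolerance = 0.004)
  # closed-form sanity: one e-fold in unit time
  expect_equal(mu_max_from_endpoint(2, 2 * exp(1), 1, 0, 2), 1.0)
  expect_error(mu_max_from_endpoint(1.49, 19.0, 5.1, -0.9, 5.05), "tF")
  expect_error(mu_max_from_endpoint(1.49, -1, 0.27, -0.9, 5.05), "positive")
})

test_that("threshold times match the published expansion periods", {
  expect_equal(time_to_threshold(gp1, 1.49, 10) - 0.11, 2.59, tolerance = 0.01)
  gp5 <- growth_params(tlag = 1.92, mu_max = 0.405, nu = 0)
  expect_equal(time_to_threshold(gp5, 1.13, 10) - 1.92, 5.38, tolerance = 0.005)
  # threshold just above the seed concentration is hit just after tlag
  expect_equal(time_to_threshold(gp1, 1.49, 1.49 * (1 + 1e-10)), gp1$tlag,
               tolerance = 1e-6)
  expect_error(time_to_threshold(gp1, 1.49, 1.2), "threshold")
})

test_that("endpoint constraint and growth law are mutual inverses", {
  set.seed(11)
  for (i in 1:25) {
    xI <- runif(1, 0.3, 2); xF <- xI * runif(1, 2, 30)
    tlag <- runif(1, 0, 1); tF <- tlag + runif(1, 2, 6)
    nu <- -runif(1, 0, 2)
    mu <- mu_max_from_endpoint(xI, xF, tlag, nu, tF)
    gp <- growth_params(tlag, mu, nu)
    expect_equal(cell_concentration(gp, xI, tF), xF, tolerance = 1e-9)
    # and the threshold time inverts the law again
    xT <- sqrt(xI * xF)
    tT <- time_to_threshold(gp, xI, xT)
    expect_equal(cell_concentration(gp, xI, tT), xT, tolerance = 1e-9)
  }
})

test_that("general formulas agree with the exponential limit for tiny |nu|", {
  tgrid <- seq(0.5, 6, by = 0.25)
  nu <- -1e-8  # at the switch-over; compare against the general expression
  mu <- 1.7; tlag <- 0.4; xI <- 1.2
  gp <- growth_params(tlag, mu, nu)
  tau <- tgrid - tlag
  general_X <- xI * (1 - mu * nu * tau)^(-1 / nu)
  general_mu <- mu / (1 - mu * nu * tau)
  expect_equal(cell_concentration(gp, xI, tgrid), general_X, tolerance = 1e-6)
  expect_equal(specific_growth_rate(gp, tgrid), general_mu, tolerance = 1e-6)
  expect_equal(mu_max_from_endpoint(xI, general_X[20], tlag, nu, tgrid[20]),
               mu, tolerance = 1e-6)
})

test_that("mu(t) X(t) equals the growth curve's derivative", {
  h <- 1e-6
  for (nu in c(-1.5, -0.922, -0.5, 0)) {
    gp <- growth_params(0.3, 1.9, nu)
    t <- seq(0.5, 5, by = 0.5)
    dX <- (cell_concentration(gp, 1.3, t + h) -
           cell_concentration(gp, 1.3, t - h)) / (2 * h)
    expect_equal(specific_growth_rate(gp, t) * cell_concentration(gp, 1.3, t),
                 dX, tolerance = 1e-4)
  }
})

test_that("growth is non-decreasing and its rate non-increasing", {
  t <- seq(0, 6, by = 0.01)
  for (nu in c(-1.8, -0.9, -0.1, 0)) {
    gp <- growth_params(0.25, 2.0, nu)
    expect_true(all(diff(cell_concentration(gp, 1.5, t)) >= 0))
    # the rate only declines once growth has started
    expect_true(all(diff(specific_growth_rate(gp, t[t >= gp$tlag])) <= 1e-12))
  }
})

test_that("set-point perfusion rate balances glucose consumption exactly", {
  t <- seq(0.3, 5, by = 0.1)
  for (nu in c(-1.3, -1, -0.5, 0)) {
    gp <- growth_params(0.27, 2.14, nu)
    lhs <- setpoint_perfusion_rate(gp, 1.49, 0.231, 25, 20, t) * 0.231 * 5
    rhs <- specific_growth_rate(gp, t) * cell_concentration(gp, 1.49, t)
    expect_equal(lhs, rhs, tolerance = 1e-14)
  }
  # nu = -1: constant; value at tlag from the run-1 numbers
  gpm1 <- growth_params(0.27, 2.14, -1)
  d <- setpoint_perfusion_rate(gpm1, 1.49, 0.231, 25, 20, c(1, 2.5, 4))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  expect_equal(setpoint_perfusion_rate(gp1, 1.49, 0.231, 25, 20, gp1$tlag),
               2.14 * 1.49 / (0.231 * 5), tolerance = 1e-12)
  # nu = -1/2: affine in time (vanishing second difference)
  gph <- growth_params(0.27, 2.14, -0.5)
  dh <- setpoint_perfusion_rate(gph, 1.49, 0.231, 25, 20, seq(1, 4, by = 0.5))
  expect_equal(diff(dh, differences = 2), rep(0, 5), tolerance = 1e-10)
  expect_error(setpoint_perfusion_rate(gp1, 1.49, 0.231, 20, 25, 1), "SI")
})

test_that("set-point lactate relaxes monotonically to its steady state", {
  pss <- lactate_steady_state(1.83, 25, 20)
  expect_equal(pss, 9.15, tolerance = 1e-12)
  expect_equal(lactate_steady_state(2.49, 26, 21), 12.45, tolerance = 1e-12)
  expect_identical(lactate_steady_state(1.83, 20, 20), 0)
  # no perfusion elapsed: unchanged; infinite perfusion: steady state
  expect_equal(lactate_setpoint_solution(1.83, 25, 20, 2.5, 0), 2.5)
  expect_equal(lactate_setpoint_solution(1.83, 25, 20, 2.5, 1e6), pss)
  # starting at the steady state stays there
  expect_equal(lactate_setpoint_solution(1.83, 25, 20, pss, c(0, 1, 7)),
               rep(pss, 3))
  # monotone and bounded between start and steady state
  p <- lactate_setpoint_solution(1.83, 25, 20, 2.5, seq(0, 10, by = 0.5))
  expect_true(all(diff(p) > 0) && all(p >= 2.5) && all(p <= pss))
  expect_error(lactate_setpoint_solution(1.83, 25, 20, 2.5, -1), "cum_D")
})

test_that("lactate-from-glucose yield is the product of the constituents", {
  expect_equal(yield_lactate_from_glucose(metabolic_params(0.272, 9.09)), 2.48,
               tolerance = 0.01)
  expect_equal(yield_lactate_from_glucose(metabolic_params(0.207, 6.83)), 1.42,
               tolerance = 0.01)
  expect_equal(yield_lactate_from_glucose(metabolic_params(0.25, 4)), 1.0)
})

test_that("invalid growth parameters are rejected", {
  expect_error(growth_params(0.2, 2, 0.1), "nu")
  expect_error(growth_params(0.2, -1, -0.5), "mu_max")
  expect_error(cell_concentration(gp1, 1.49, NaN), "finite")
  expect_error(cell_concentration(gp1, -1, 1), "xI")
})
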