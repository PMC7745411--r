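closed_form_logistic <- function(r, N0, K, t) {
  K * N0 * exp(r * t) / (K + N0 * (exp(r * t) - 1))
}

test_that("fixed points are preserved for arbitrary rate curves", {
  cur <- rate_curve(c(0.8, -0.3, 1.5), 0, 8)
  at_K <- solve_deterministic(culture_model(3e6, 3e6), cur, c(0, 2.5, 5, 8))
  expect_equal(at_K$size, rep(3e6, 4))
  at_0 <- solve_deterministic(culture_model(3e6, 0), cur, c(0, 5))
  expect_equal(at_0$size, c(0, 0))
  flat <- solve_deterministic(culture_model(3e6, 1e5), rate_curve(0), c(0, 8))
  expect_equal(flat$size, c(1e5, 1e5))
})

test_that("constant-rate solutions match the closed-form logistic", {
  tr <- solve_deterministic(culture_model(3e6, 1e5), rate_curve(0.5), c(0, 4))
  expect_equal(tr$size[2], closed_form_logistic(0.5, 1e5, 3e6, 4),
               tolerance = 1e-6)
  set.seed(1)
  for (i in 1:25) {
    r <- runif(1, -1, 2)
    K <- 10^runif(1, 3, 7)
    # overgrown cultures only with r > 0: N0 > K with r < 0 blows up
    N0 <- K * runif(1, 0.001, if (r < 0) 1 else 2)
    t <- runif(1, 0.1, 10)
    got <- solve_deterministic(culture_model(K, N0), rate_curve(r), c(0, t))$size[2]
    want <- closed_form_logistic(r, N0, K, t)
    expect_lt(abs(got - want) / want, 1e-6)
  }
})

test_that("monotone approach to carrying capacity and decay for r < 0", {
  times <- seq(0, 10, by = 0.5)
  up <- solve_deterministic(culture_model(1e6, 1e4), rate_curve(0.6), times)$size
  expect_true(all(diff(up) > 0))
  expect_true(all(up < 1e6))
  down <- solve_deterministic(culture_model(1e6, 2e6), rate_curve(0.6), times)$size
  expect_true(all(diff(down) < 0))
  expect_true(all(down > 1e6))
  dying <- solve_deterministic(culture_model(1e6, 1e4), rate_curve(-0.4), times)$size
  expect_true(all(diff(dying) < 0))
  expect_lt(dying[length(dying)], 1e4 * exp(-0.4 * 9))
})

test_that("closed-form solution agrees with adaptive ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  for (i in 1:10) {
    k <- sample(1:3, 1)
    over <- runif(1) < 0.3
    # overgrown cultures with negative rates blow up in finite time (true of
    # the ODE as well), so negative rates are only drawn for N0 < K
    vals <- if (over) runif(k, 0.1, 2) else runif(k, -0.5, 2)
    cur <- rate_curve(vals, 0, if (k > 1) 8 else 0)
    K <- 10^runif(1, 4, 7)
    N0 <- K * if (over) runif(1, 1, 1.5) else runif(1, 0.005, 1)
    times <- seq(0, 8, by = 1)
    ode <- deSolve::lsoda(
      y = c(N = N0), times = times,
      func = function(t, y, p) list(rate_at(cur, t) * y[1] * (1 - y[1] / K)),
      rtol = 1e-10, atol = 1e-4)
    got <- solve_deterministic(culture_model(K, N0), cur, times)$size
    expect_lt(max(abs(got - ode[, "N"]) / pmax(ode[, "N"], 1)), 1e-5)
  }
})

test_that("invalid time grids are rejected", {
  m <- culture_model(1e6, 1e4)
  expect_error(solve_deterministic(m, rate_curve(1), c(2, 1)), "sorted")
  expect_error(solve_deterministic(m, rate_curve(1), c(-1, 2)), ">= 0")
})

test_that("culture_model validates K and N0", {
  expect_error(culture_model(0, 10), "positive")
  expect_error(culture_model(1e6, -5), "non-negative")
  expect_silent(culture_model(1e6, 2e6))  # N0 > K is allowed
})
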