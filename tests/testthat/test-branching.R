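test_that("extinction is absorbing and N0 = 0 stays at zero", {
  cfg <- branching_config(culture_model(100, 0), rate_curve(1), t_end = 3)
  tr <- simulate_branching(cfg)
  expect_equal(tr$size, c(0, 0))
  # once a trajectory hits zero it never leaves it
  cfg2 <- branching_config(culture_model(10, 2), rate_curve(2.5), t_end = 50,
                           seed = 7)
  tr2 <- simulate_branching(cfg2)
  if (any(tr2$size == 0)) {
    first0 <- which(tr2$size == 0)[1]
    expect_true(all(tr2$size[first0:length(tr2$size)] == 0))
  }
})

test_that("a single cell cannot die first: death hazard is zero at N = 1", {
  for (s in 1:15) {
    cfg <- branching_config(culture_model(1e3, 1), rate_curve(1.5), t_end = 10,
                            seed = s)
    tr <- simulate_branching(cfg)
    expect_gte(tr$size[2], tr$size[1])  # first event is a birth
    expect_equal(tr$size[2], 2)
  }
})

test_that("identical seeds give identical trajectories", {
  cfg <- branching_config(culture_model(5e3, 50), rate_curve(c(0.2, 1.2), 0, 6),
                          t_end = 6, seed = 99)
  a <- simulate_branching(cfg)
  b <- simulate_branching(cfg)
  expect_identical(a, b)
})

test_that("negative rates are rejected on the stochastic path", {
  expect_error(branching_config(culture_model(1e3, 10), rate_curve(-0.1), 5),
               "non-negative")
  expect_error(branching_config(culture_model(1e3, 10),
                                rate_curve(c(0.5, -0.5), 0, 5), 5),
               "non-negative")
})

test_that("runaway event counts trip the guard", {
  cfg <- branching_config(culture_model(1e6, 1e4), rate_curve(2), t_end = 20,
                          max_events = 1000)
  expect_error(simulate_branching(cfg), "max_events")
})

test_that("ensemble replicates start at N0 and reduce to single runs", {
  cfg <- branching_config(culture_model(2e3, 40), rate_curve(0.8), t_end = 4,
                          seed = 5)
  em <- ensemble(cfg, n_reps = 20, times = c(0, 2, 4))
  expect_equal(dim(em), c(20, 3))
  expect_true(all(em[, 1] == 40))
  # n_reps = 1 is one simulate_branching trajectory sampled on the grid
  set.seed(cfg$seed)
  seed1 <- sample.int(.Machine$integer.max - 1L, 1)
  cfg1 <- cfg; cfg1$seed <- seed1
  tr <- simulate_branching(cfg1)
  one <- ensemble(cfg, n_reps = 1, times = c(0, 2, 4))
  expect_equal(as.numeric(one),
               approx(tr$time, tr$size, xout = c(0, 2, 4),
                      method = "constant", rule = 2)$y)
})

test_that("ensemble mean tracks the deterministic solution, closer as K grows", {
  # relative deviation of the stochastic mean from the logistic solution
  # shrinks with carrying capacity (deterministic limit)
  dev_for_K <- function(K, n_reps) {
    cfg <- branching_config(culture_model(K, round(K / 100)), rate_curve(0.7),
                            t_end = 5, seed = 31)
    em <- ensemble(cfg, n_reps, times = c(0, 5))
    det <- solve_deterministic(culture_model(K, round(K / 100)),
                               rate_curve(0.7), c(0, 5))$size[2]
    abs(mean(em[, 2]) - det) / det
  }
  expect_lt(dev_for_K(1e4, 100), dev_for_K(1e2, 100) + 0.02)
  expect_lt(dev_for_K(1e4, 100), 0.05)
})

test_that("long runs hover near the carrying capacity", {
  cfg <- branching_config(culture_model(2e3, 2e3), rate_curve(1), t_end = 10,
                          seed = 13)
  em <- ensemble(cfg, n_reps = 30, times = seq(5, 10, by = 1))
  expect_lt(abs(mean(em) - 2e3) / 2e3, 0.05)
})

test_that("time-varying hazards follow the rate curve", {
  # with r(t) = 0 on the first half of the window, no events can occur there
  cur <- rate_curve(c(0, 0, 2, 2), 0, 6)
  cfg <- branching_config(culture_model(500, 20), cur, t_end = 6, seed = 3)
  tr <- simulate_branching(cfg)
  ev <- tr$time[tr$time > 0 & tr$time < 6]
  expect_true(all(ev > 2))  # cumulative rate is 0 until t = 2
  expect_gt(length(ev), 0)
})
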