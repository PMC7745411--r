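test_that("distance matches the variance-stabilised formula", {
  expect_equal(abc_distance(c(4, 9), c(1, 4)), sqrt(2))
  expect_equal(abc_distance(c(4, 9), c(4, 9)), 0)
  a <- c(12, 80, 300); b <- c(20, 60, 350)
  expect_equal(abc_distance(a, b), abc_distance(b, a))
  expect_equal(abc_distance(a, b, kind = "euclid"), sqrt(sum((a - b)^2)))
  s1 <- count_series("x", c(0, 1), c(4, 9), sampling_scheme(1))
  s2 <- count_series("x", c(0, 2), c(1, 4), sampling_scheme(1))
  expect_error(abc_distance(s1, s2), "time grids")
  expect_error(abc_distance(c(1, 2), c(1, 2, 3)), "length")
})

test_that("config and prior constructors validate invariants", {
  expect_error(prior_spec(rate_min = 3, rate_max = 1), "rate_min")
  expect_error(prior_spec(control_points = integer(0)), "non-empty")
  expect_error(abc_config(n_particles = 5), "n_particles")
  expect_error(abc_config(epsilon_quantile = 1), "epsilon_quantile")
})

test_that("acceptance thresholds are non-increasing across generations", {
  gen <- generate_scenario(builtin_scenarios(seed = 2)$constant)
  post <- run_abc_smc(gen$series, 3e6, prior_spec(control_points = 1),
                      quick_abc(seed = 4))
  eps <- post$eps_history
  expect_equal(length(eps), 4)
  expect_true(all(diff(eps[-1]) <= 0))
  expect_equal(sum(post$model_prob), 1)
  m <- post$models[["1"]]
  expect_equal(sum(m$weights), 1)
  expect_true(all(m$weights >= 0))
})

test_that("identical seed and config give an identical posterior", {
  gen <- generate_scenario(builtin_scenarios(seed = 6)$constant)
  p1 <- run_abc_smc(gen$series, 3e6, prior_spec(control_points = c(1, 2)),
                    quick_abc(seed = 20, n_particles = 60, n_generations = 3))
  p2 <- run_abc_smc(gen$series, 3e6, prior_spec(control_points = c(1, 2)),
                    quick_abc(seed = 20, n_particles = 60, n_generations = 3))
  expect_identical(p1$models, p2$models)
  expect_identical(p1$model_prob, p2$model_prob)
})

test_that("a point prior with noiseless data returns that point with mass 1", {
  truth <- 0.8
  n0 <- 1000
  s <- scenario("exact", rate_curve(truth), culture_model(5e4, n0),
                times = 0:4, scheme = sampling_scheme(1),
                noise = counting_noise("none"))
  gen <- generate_scenario(s)
  prior <- prior_spec(rate_min = truth, rate_max = truth, control_points = 1,
                      n0_multipliers = c(1, 1))
  post <- run_abc_smc(gen$series, 5e4, prior,
                      quick_abc(seed = 1, n_particles = 30, n_generations = 3),
                      noise = counting_noise("none"))
  m <- post$models[["1"]]
  expect_true(all(m$samples[, "r1"] == truth))
  expect_equal(sum(m$weights) * m$probability, 1)
  expect_equal(unname(post$model_prob), 1)
})

test_that("the N0 prior brackets the first observation's point estimate", {
  gen <- generate_scenario(builtin_scenarios(seed = 12)$constant)
  pe <- point_estimate_population(gen$series$count[1],
                                  sampling_scheme(c(0.01, 0.02)))
  post <- run_abc_smc(gen$series, 3e6, prior_spec(control_points = 1),
                      quick_abc(seed = 3, n_particles = 60, n_generations = 3))
  n0s <- post$models[["1"]]$samples[, 1]
  expect_true(all(n0s >= 0.2 * pe & n0s <= 5 * pe))
})

test_that("more observations contract the constant-rate posterior", {
  width_for <- function(times, seed) {
    s <- scenario("w", rate_curve(1.0), times = times, seed = seed)
    gen <- generate_scenario(s)
    post <- run_abc_smc(gen$series, 3e6, prior_spec(control_points = 1),
                        quick_abc(seed = seed + 100, n_particles = 150,
                                  n_generations = 5))
    m <- post$models[["1"]]
    h <- hpdi(m$samples[, "r1"], 0.89, m$weights)
    h$high - h$low
  }
  sparse <- mean(vapply(1:3, function(s) width_for(seq(0, 8, 2), s), numeric(1)))
  dense <- mean(vapply(1:3, function(s) width_for(seq(0, 8, 1), s), numeric(1)))
  expect_lt(dense, sparse)
})

test_that("the stochastic simulator path runs and recovers the right scale", {
  s <- scenario("stoch", rate_curve(0.9), culture_model(2e4, 500),
                times = 0:5, scheme = sampling_scheme(0.1),
                noise = counting_noise("none"), seed = 2)
  gen <- generate_scenario(s)
  post <- run_abc_smc(gen$series, 2e4, prior_spec(control_points = 1),
                      quick_abc(seed = 9, n_particles = 40, n_generations = 3,
                                simulator = "stochastic"),
                      noise = counting_noise("none"))
  m <- post$models[["1"]]
  est <- sum(m$samples[, "r1"] * m$weights)
  expect_gt(est, 0.4)
  expect_lt(est, 1.6)
})

test_that("posterior bands collapse to the sample for a one-particle posterior", {
  post <- point_posterior(rates = c(0.4, 0.9))
  band <- posterior_rate_band(post, times = c(0, 4, 8))
  expect_equal(band$rate$low, band$rate$high)
  expect_equal(band$rate$median, c(0.4, 0.65, 0.9))
  # population band equals the deterministic curve for the single particle
  cur <- rate_curve(c(0.4, 0.9), 0, 8)
  det <- solve_deterministic(culture_model(3e6, 1e5), cur, c(0, 4, 8))
  expect_equal(band$population$minimal$median, det$size)
})
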