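test_that("expected counts and point estimates invert each other", {
  sch <- sampling_scheme(c(0.01, 0.02))
  expect_equal(expected_count(95000, sch), 19)
  expect_equal(point_estimate_population(19, sch), 95000)
  expect_equal(expected_count(0, sch), 0)
  expect_equal(point_estimate_population(0, sch), 0)
  whole <- sampling_scheme(1)
  expect_equal(expected_count(12345, whole), 12345)
  expect_equal(point_estimate_population(777, whole), 777)
})

test_that("scheme and noise specs validate their domains", {
  expect_error(sampling_scheme(numeric(0)))
  expect_error(sampling_scheme(c(0.1, 0)))
  expect_error(sampling_scheme(1.5))
  expect_error(counting_noise("normal_binomial", 1))
  expect_error(counting_noise("normal_binomial", -0.1))
  expect_error(simulate_observation(-5, sampling_scheme(0.5)))
})

test_that("zero population always observes zero", {
  set.seed(1)
  sch <- sampling_scheme(c(0.01, 0.02))
  expect_true(all(simulate_observation(rep(0, 100), sch,
                                       counting_noise("normal_binomial")) == 0))
})

test_that("nested Poisson sampling preserves the expected count", {
  set.seed(2)
  sch <- sampling_scheme(c(0.01, 0.02))
  draws <- simulate_observation(rep(95000, 1e5), sch)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 19), 3 * se)
  # with zero-mean counting noise the mean is approximately preserved too
  set.seed(3)
  noisy <- simulate_observation(rep(95000, 1e5), sch,
                                counting_noise("normal_binomial", 0.05))
  expect_lt(abs(mean(noisy) - 19), 4 * sd(noisy) / sqrt(length(noisy)) + 0.1)
})

test_that("counting noise adds variance on top of sampling noise", {
  sch <- sampling_scheme(c(0.05))
  set.seed(4)
  plain <- simulate_observation(rep(5e4, 2e4), sch)
  set.seed(4)
  noisy <- simulate_observation(rep(5e4, 2e4), sch,
                                counting_noise("normal_binomial", 0.05))
  expect_gte(var(noisy), var(plain))
})

test_that("nested Poisson thinning equals a single Poisson with the product rate", {
  # Poisson(Poisson(N f1) f2) is distributed as Poisson(N f1 f2): compare the
  # nested draws with the closed-form pmf by a goodness-of-fit test
  set.seed(5)
  nested <- simulate_observation(rep(95000, 1e5), sampling_scheme(c(0.01, 0.02)))
  lambda <- 95000 * 0.01 * 0.02
  breaks <- c(-Inf, 8:30, Inf)
  obs <- table(cut(nested, breaks))
  p <- diff(ppois(c(-Inf, 8:30, Inf), lambda))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p))
  expect_gt(gof$p.value, 1e-4)
})

test_that("haemocytometer volume bookkeeping gives the worked fractions", {
  fr <- haemocytometer_fractions(culture_volume = 1000, sample_volume = 10,
                                 counted_volume = 0.4, dilution = 2)
  expect_equal(unname(fr), c(0.01, 0.02))
  # 0.4 uL counted at 1:1 dilution is 0.2 uL undiluted; 10 uL * 0.02 = 0.2 uL
  expect_equal(10 * fr[["sample2"]], 0.4 / 2)
})

test_that("hyperbolic inhibition halves the rate at the IC50", {
  expect_equal(inhibited_rate(1.0, conc = 240, ic50 = 240), 0.5)
  expect_equal(inhibited_rate(1.0, conc = 0, ic50 = 240), 1.0)
  expect_lt(inhibited_rate(1.0, conc = 480, ic50 = 240), 0.5)
})
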