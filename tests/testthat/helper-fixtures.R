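# Shared fixtures built in code at test time.

table1_series <- function() {
  count_series("minimal", time = c(0, 2, 4, 6, 8),
               count = c(19, 105, 403, 529, 591),
               fractions = sampling_scheme(c(0.01, 0.02)))
}

write_table1_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c("name,time,count,sample1,sample2",
               "minimal,0.0,19,0.01,0.02",
               "minimal,2.0,105,0.01,0.02",
               "minimal,4.0,403,0.01,0.02",
               "minimal,6.0,529,0.01,0.02",
               "minimal,8.0,591,0.01,0.02"), path)
  path
}

write_minimal_toml <- function(path = tempfile(fileext = ".toml"), extra = character(0)) {
  writeLines(c("# minimal run configuration",
               "carrying_capacity = 3e6  # cells",
               extra), path)
  path
}

quick_abc <- function(seed = 1, n_particles = 100, n_generations = 4, ...) {
  abc_config(n_particles = n_particles, n_generations = n_generations,
             seed = seed, ...)
}

# hand-built posterior with a single known particle, for reporting tests
point_posterior <- function(n0 = 1e5, rates = c(0.4, 0.9), K = 3e6,
                            series = table1_series()) {
  k <- length(rates)
  samples <- matrix(c(n0, rates), nrow = 1,
                    dimnames = list(NULL, c("n0:minimal", paste0("r", seq_len(k)))))
  models <- list(list(k = k, samples = samples, weights = 1, probability = 1,
                      distances = 0))
  names(models) <- as.character(k)
  structure(list(models = models,
                 model_prob = stats::setNames(1, as.character(k)),
                 eps_history = Inf, attempts = 1L,
                 series = list(series), K = K, t0 = min(series$time),
                 t_span = diff(range(series$time)),
                 prior = prior_spec(), cfg = quick_abc(),
                 noise = counting_noise("none")),
            class = "abc_posterior")
}
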