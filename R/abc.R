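#' Prior specification for the rate control points
#'
#' Uniform priors over a user-defined range are placed on every growth-rate
#' control point. The number of control points is itself uncertain: one
#' (constant rate), two (linear trend) and/or three (linear with a central
#' breakpoint) are treated as competing models with a uniform model prior.
#' The initial population N0 is a latent parameter with a uniform prior
#' centred on the point estimate of the first observation, spanning
#' \code{n0_multipliers} times that estimate.
#'
#' @param rate_min,rate_max prior range for each control point
#'   (divisions/cell/day); defaults 0.01 and 3.0.
#' @param control_points subset of \{1, 2, 3\} (larger values allowed but not
#'   defaulted).
#' @param n0_multipliers length-2 multipliers of the first observation's
#'   population point estimate bounding the N0 prior; default (0.2, 5).
#' @return an object of class \code{prior_spec}.
#' @export
prior_spec <- function(rate_min = 0.01, rate_max = 3.0,
                       control_points = c(1, 2, 3),
                       n0_multipliers = c(0.2, 5)) {
  if (!is.numeric(rate_min) || !is.numeric(rate_max) || rate_min > rate_max)
    stop("rate_min must be <= rate_max")
  control_points <- sort(unique(as.integer(control_points)))
  if (length(control_points) < 1 || any(control_points < 1))
    stop("control_points must be a non-empty set of positive integers")
  if (length(n0_multipliers) != 2 || n0_multipliers[1] > n0_multipliers[2] ||
      any(n0_multipliers <= 0))
    stop("n0_multipliers must be two increasing positive numbers")
  structure(list(rate_min = rate_min, rate_max = rate_max,
                 control_points = control_points,
                 n0_multipliers = as.numeric(n0_multipliers)),
            class = "prior_spec")
}

#' ABC-SMC sampler configuration
#'
#' @param n_particles particles per generation (>= 10).
#' @param n_generations number of SMC generations (>= 1).
#' @param epsilon_quantile quantile of the accepted distances used as the
#'   next generation's acceptance threshold, in (0, 1). The default 0.25
#'   reaches the observation-noise floor within about six generations on
#'   typical count series; larger values shrink the threshold more slowly and
#'   need more generations, smaller values risk stalling the sampler below
#'   the noise floor.
#' @param distance \code{"sqrt_euclid"} (Euclidean distance between
#'   square-root-transformed counts; variance-stabilising for Poisson counts)
#'   or \code{"euclid"}.
#' @param simulator \code{"deterministic"} (exact logistic solution) or
#'   \code{"stochastic"} (logistic branching process).
#' @param n_parallel worker count accepted for interface compatibility;
#'   execution is sequential so results never depend on it.
#' @param seed integer seed; identical seed and config give an identical
#'   posterior.
#' @return an object of class \code{abc_config}.
#' @export
abc_config <- function(n_particles = 200, n_generations = 6,
                       epsilon_quantile = 0.25,
                       distance = c("sqrt_euclid", "euclid"),
                       simulator = c("deterministic", "stochastic"),
                       n_parallel = 4, seed = 1) {
  distance <- match.arg(distance)
  simulator <- match.arg(simulator)
  if (n_particles < 10) stop("n_particles must be >= 10")
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (epsilon_quantile <= 0 || epsilon_quantile >= 1)
    stop("epsilon_quantile must be in (0, 1)")
  if (n_parallel < 1) stop("n_parallel must be >= 1")
  structure(list(n_particles = as.integer(n_particles),
                 n_generations = as.integer(n_generations),
                 epsilon_quantile = epsilon_quantile,
                 distance = distance, simulator = simulator,
                 n_parallel = as.integer(n_parallel),
                 seed = as.integer(seed)),
            class = "abc_config")
}

#' Distance between an observed and a simulated count series
#'
#' Default \code{sqrt_euclid}: the Euclidean distance between element-wise
#' square-rooted counts, a variance-stabilising transform appropriate for
#' Poisson-dominated counting noise. Plain Euclidean is selectable. The two
#' series must share their time grid and sampling schemes.
#'
#' @param observed,simulated \code{\link{count_series}} objects on identical
#'   grids, or bare numeric count vectors of equal length.
#' @param kind \code{"sqrt_euclid"} or \code{"euclid"}.
#' @return non-negative distance; zero iff the counts are identical.
#' @examples
#' abc_distance(c(4, 9), c(1, 4))  # sqrt(2)
#' @export
abc_distance <- function(observed, simulated,
                         kind = c("sqrt_euclid", "euclid")) {
  kind <- match.arg(kind)
  if (inherits(observed, "count_series") && inherits(simulated, "count_series")) {
    if (!isTRUE(all.equal(observed$time, simulated$time)))
      stop("observed and simulated series are on different time grids")
    observed <- observed$count
    simulated <- simulated$count
  }
  if (length(observed) != length(simulated))
    stop("count vectors differ in length")
  if (kind == "sqrt_euclid") {
    observed <- sqrt(observed); simulated <- sqrt(simulated)
  }
  sqrt(sum((observed - simulated)^2))
}

# ---- internal: forward model over a group of series ------------------------

# Precomputed per-group context shared by every particle evaluation.
abc_context <- function(series_list, K, prior, cfg, noise) {
  t0 <- min(vapply(series_list, function(s) s$time[1], numeric(1)))
  t_last <- max(vapply(series_list, function(s) max(s$time), numeric(1)))
  ser <- lapply(series_list, function(s) {
    fm <- fraction_matrix(s)
    pe <- point_estimate_population(s$count[1], row_scheme(s, 1))
    list(name = s$name[1], times_rel = s$time - t0, counts = s$count,
         fm = fm, n0_lo = prior$n0_multipliers[1] * pe,
         n0_hi = prior$n0_multipliers[2] * pe)
  })
  rate_lo <- if (cfg$simulator == "stochastic") max(prior$rate_min, 0) else prior$rate_min
  list(series = ser, K = K, t0 = t0, t_span = t_last - t0,
       rate_lo = rate_lo, rate_hi = prior$rate_max,
       obs = unlist(lapply(ser, `[[`, "counts")),
       noise = noise, cfg = cfg)
}

# Parameter bounds for a model with k control points:
# (n0 per series, then k rate values).
param_bounds <- function(ctx, k) {
  lo <- c(vapply(ctx$series, `[[`, numeric(1), "n0_lo"),
          rep(ctx$rate_lo, k))
  hi <- c(vapply(ctx$series, `[[`, numeric(1), "n0_hi"),
          rep(ctx$rate_hi, k))
  names(lo) <- names(hi) <- c(paste0("n0:", vapply(ctx$series, `[[`, character(1), "name")),
                              paste0("r", seq_len(k)))
  list(lo = lo, hi = hi)
}

theta_curve <- function(ctx, theta, k) {
  vals <- theta[length(theta) - k + seq_len(k)]
  if (k == 1) rate_curve(vals) else rate_curve(vals, 0, ctx$t_span)
}

# Simulate counts for one particle; uses the current RNG stream.
forward_counts <- function(ctx, theta, k) {
  ns <- length(ctx$series)
  curve <- theta_curve(ctx, theta, k)
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    se <- ctx$series[[s]]
    if (ctx$cfg$simulator == "stochastic") {
      model <- culture_model(ctx$K, max(0, theta[s]))
      tr <- branching_run(model, curve, max(se$times_rel, 1e-9))
      N <- stats::approx(tr$time, tr$size, xout = se$times_rel,
                         method = "constant", rule = 2)$y
    } else {
      R <- cumulative_rate(curve, se$times_rel)
      N <- if (theta[s] <= 0) rep(0, length(R))
           else logistic_closed_form(theta[s], ctx$K, R)
    }
    cnt <- N
    for (j in seq_len(ncol(se$fm))) cnt <- stats::rpois(length(cnt), cnt * se$fm[, j])
    out[[s]] <- apply_counting_noise(cnt, ctx$noise)
  }
  unlist(out)
}

#' Invert the forward model by ABC sequential Monte Carlo
#'
#' Fits the time-varying logistic growth model to one or more count series
#' (a group shares one rate curve, with an independent initial population per
#' series). Generation 1 samples particles from the prior; each later
#' generation resamples particles by weight, perturbs them with a
#' component-wise Gaussian kernel whose scale adapts to the previous
#' generation, simulates the full forward model (growth, nested-Poisson
#' sampling, counting noise) at the observed times and schemes, and accepts
#' particles whose distance to the observed counts is at most the current
#' threshold. The threshold is the \code{epsilon_quantile} of the previous
#' generation's accepted distances, so it is non-increasing. When several
#' control-point counts are requested they compete as models under a uniform
#' model prior, and per-model posterior mass is reported.
#'
#' @param data a \code{\link{count_series}} or a list of them (one group).
#' @param model a \code{\link{culture_model}} or a single positive number
#'   giving the carrying capacity K; the initial population is latent and
#'   inferred per series.
#' @param prior a \code{\link{prior_spec}}.
#' @param cfg an \code{\link{abc_config}}.
#' @param noise a \code{\link{counting_noise}} used inside the forward model.
#' @param verbose log per-generation thresholds and acceptance counts.
#' @return an object of class \code{abc_posterior}: per-model weighted
#'   samples, model posterior probabilities, the acceptance-threshold
#'   history, and the inputs needed for prediction and reporting.
#' @export
run_abc_smc <- function(data, model, prior = prior_spec(), cfg = abc_config(),
                        noise = counting_noise(), verbose = FALSE) {
  if (inherits(data, "count_series")) data <- list(data)
  stopifnot(length(data) >= 1)
  if (any(vapply(data, nrow, integer(1)) < 2))
    stop("each series needs at least 2 count records")
  K <- if (inherits(model, "culture_model")) model$K else as.numeric(model)
  if (!is.numeric(K) || K <= 0) stop("a positive carrying capacity K is required")
  ctx <- abc_context(data, K, prior, cfg, noise)
  models <- prior$control_points
  M <- length(models)
  n <- cfg$n_particles
  bounds <- lapply(models, function(k) param_bounds(ctx, k))
  names(bounds) <- as.character(models)

  set.seed(cfg$seed)
  # generation 1: straight prior samples, uniform weights
  midx <- sample.int(M, n, replace = TRUE)
  theta <- vector("list", n)
  dist <- numeric(n)
  for (i in seq_len(n)) {
    b <- bounds[[midx[i]]]
    th <- stats::runif(length(b$lo), b$lo, b$hi)
    names(th) <- names(b$lo)
    theta[[i]] <- th
    dist[i] <- abc_distance(ctx$obs, forward_counts(ctx, th, models[midx[i]]),
                            kind = cfg$distance)
  }
  w <- rep(1 / n, n)
  eps_history <- Inf
  attempts_history <- n

  for (gen in seq_len(cfg$n_generations - 1L)) {
    eps <- stats::quantile(dist, cfg$epsilon_quantile, names = FALSE, type = 7)
    # adaptive kernel scale per model and component
    kern <- lapply(seq_len(M), function(m) {
      sel <- which(midx == m)
      b <- bounds[[m]]
      if (!length(sel)) return(NULL)
      th <- do.call(rbind, theta[sel])
      wm <- w[sel] / sum(w[sel])
      mu <- colSums(th * wm)
      v <- colSums(t(t(th) - mu)^2 * wm)
      sd <- pmax(sqrt(2 * v), 1e-8 * (b$hi - b$lo))
      sd[b$hi == b$lo] <- 0  # degenerate (point) prior: never perturb
      sd
    })
    new_theta <- vector("list", n)
    new_midx <- integer(n)
    new_dist <- numeric(n)
    acc <- 0L
    att <- 0L
    max_att <- 500L * n
    while (acc < n) {
      att <- att + 1L
      if (att > max_att)
        stop("no particle accepted within the attempt budget at generation ",
             gen + 1L, "; the epsilon schedule is too aggressive for this data")
      j <- sample.int(n, 1L, prob = w)
      m <- midx[j]
      b <- bounds[[m]]
      th <- theta[[j]] + ifelse(kern[[m]] > 0,
                                stats::rnorm(length(b$lo), 0, pmax(kern[[m]], 1e-300)),
                                0)
      if (any(th < b$lo | th > b$hi)) next
      d <- abc_distance(ctx$obs, forward_counts(ctx, th, models[m]),
                        kind = cfg$distance)
      if (d <= eps) {
        acc <- acc + 1L
        names(th) <- names(b$lo)
        new_theta[[acc]] <- th
        new_midx[acc] <- m
        new_dist[acc] <- d
      }
    }
    # SMC importance weights: uniform model prior x uniform parameter prior
    # over the kernel-mixture proposal within the particle's model
    new_w <- numeric(n)
    for (m in seq_len(M)) {
      sel_new <- which(new_midx == m)
      if (!length(sel_new)) next
      sel_old <- which(midx == m)
      b <- bounds[[m]]
      r <- b$hi - b$lo
      prior_dens <- (1 / M) * prod(ifelse(r > 0, 1 / r, 1))
      th_old <- do.call(rbind, theta[sel_old])
      w_old <- w[sel_old]
      sd <- kern[[m]]
      live <- which(sd > 0)  # point-prior components carry no kernel mass
      for (i in sel_new) {
        z <- t(t(th_old[, live, drop = FALSE]) - new_theta[[i]][live])
        dk <- matrix(stats::dnorm(z, 0, rep(sd[live], each = nrow(z)), log = TRUE),
                     nrow = nrow(z))
        logk <- rowSums(dk)
        denom <- sum(w_old * exp(logk - max(logk))) * exp(max(logk))
        new_w[i] <- prior_dens / denom
      }
    }
    if (!any(is.finite(new_w)) || sum(new_w) <= 0)
      new_w <- rep(1 / n, n)
    theta <- new_theta
    midx <- new_midx
    dist <- new_dist
    w <- new_w / sum(new_w)
    eps_history <- c(eps_history, eps)
    attempts_history <- c(attempts_history, att)
    if (verbose)
      message(sprintf("generation %d: eps = %.4g, accepted %d/%d attempts",
                      gen + 1L, eps, n, att))
  }

  per_model <- lapply(seq_len(M), function(m) {
    sel <- which(midx == m)
    if (!length(sel))
      return(list(k = models[m], samples = NULL, weights = numeric(0),
                  probability = 0))
    list(k = models[m],
         samples = do.call(rbind, theta[sel]),
         weights = w[sel] / sum(w[sel]),
         probability = sum(w[sel]),
         distances = dist[sel])
  })
  names(per_model) <- as.character(models)
  structure(list(models = per_model,
                 model_prob = stats::setNames(
                   vapply(per_model, `[[`, numeric(1), "probability"),
                   as.character(models)),
                 eps_history = eps_history,
                 attempts = attempts_history,
                 series = data, K = K, t0 = ctx$t0, t_span = ctx$t_span,
                 prior = prior, cfg = cfg, noise = noise),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> %d series, K = %g\n", length(x$series), x$K))
  cat("  model probabilities:",
      paste(sprintf("%s-point: %.3f", names(x$model_prob), x$model_prob),
            collapse = ", "), "\n")
  cat("  epsilon history:", paste(signif(x$eps_history, 3), collapse = " -> "), "\n")
  invisible(x)
}

# pooled samples across models with overall weights; returns list of
# (k, theta, weight) rows flattened
pooled_particles <- function(post) {
  out <- list()
  for (m in post$models) {
    if (is.null(m$samples)) next
    out[[length(out) + 1]] <- list(k = m$k, samples = m$samples,
                                   weights = m$weights * m$probability)
  }
  out
}

#' Posterior credibility bands for the rate and population curves
#'
#' Evaluates r(t) (and the deterministic population curve per series) for
#' every weighted posterior sample, pooled across the competing
#' control-point models, and returns per-time HPD bands together with the
#' weighted posterior median.
#'
#' @param post an \code{\link{run_abc_smc}} posterior.
#' @param times times (days, on the original data timescale) at which to
#'   evaluate; default a 101-point grid over the observation window.
#' @param mass HPD mass (default 0.89).
#' @return list with \code{rate}: data frame (time, median, low, high), and
#'   \code{population}: a named list of such data frames, one per series.
#' @export
posterior_rate_band <- function(post, times = NULL, mass = 0.89) {
  stopifnot(inherits(post, "abc_posterior"))
  pp <- pooled_particles(post)
  if (!length(pp)) stop("empty posterior")
  if (is.null(times))
    times <- seq(post$t0, post$t0 + post$t_span, length.out = 101)
  t_rel <- times - post$t0

  # per-sample rate curves evaluated on the grid
  rate_mat <- NULL
  wts <- NULL
  tabs <- list()
  for (blk in pp) {
    k <- blk$k
    ns <- nrow(blk$samples)
    rv <- blk$samples[, ncol(blk$samples) - k + seq_len(k), drop = FALSE]
    rm_blk <- matrix(NA_real_, ns, length(t_rel))
    for (i in seq_len(ns)) {
      cur <- if (k == 1) rate_curve(rv[i, ]) else rate_curve(rv[i, ], 0, post$t_span)
      rm_blk[i, ] <- rate_at(cur, t_rel)
      tabs[[length(tabs) + 1]] <- list(tab = cum_rate_table(cur), row = blk$samples[i, ])
    }
    rate_mat <- rbind(rate_mat, rm_blk)
    wts <- c(wts, blk$weights)
  }
  wts <- wts / sum(wts)

  band <- function(vals_mat) {
    lo <- hi <- med <- numeric(ncol(vals_mat))
    for (j in seq_len(ncol(vals_mat))) {
      h <- hpdi(vals_mat[, j], mass = mass, weights = wts)
      lo[j] <- h$low; hi[j] <- h$high
      med[j] <- weighted_quantile(vals_mat[, j], wts, 0.5)
    }
    data.frame(time = times, median = med, low = lo, high = hi)
  }
  rate_band <- band(rate_mat)

  pop <- list()
  series_names <- vapply(post$series, function(s) s$name[1], character(1))
  for (s in seq_along(series_names)) {
    pm <- matrix(NA_real_, length(tabs), length(t_rel))
    for (i in seq_along(tabs)) {
      n0 <- tabs[[i]]$row[s]
      R <- pmax(cum_rate_eval(tabs[[i]]$tab, pmax(t_rel, 0)), -700)
      pm[i, ] <- logistic_closed_form(n0, post$K, R)
    }
    pop[[series_names[s]]] <- band(pm)
  }
  list(rate = rate_band, population = pop)
}

weighted_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  x[ord][findInterval(p, cw, left.open = TRUE) + 1]
}
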