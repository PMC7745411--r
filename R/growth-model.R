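#' Culture model: carrying capacity and initial population
#'
#' Shared parameters of both simulators. The carrying capacity K is the
#' largest population the culture sustains if left alone and must be supplied
#' by the user; it is not inferred. N0 may exceed K: an overgrown culture
#' shrinks back toward K.
#'
#' @param carrying_capacity K, in cells (> 0).
#' @param initial_population N0, in cells (>= 0).
#' @return an object of class \code{culture_model}.
#' @export
culture_model <- function(carrying_capacity, initial_population) {
  if (!is.numeric(carrying_capacity) || length(carrying_capacity) != 1 ||
      !is.finite(carrying_capacity) || carrying_capacity <= 0)
    stop("carrying_capacity must be a single positive number")
  if (!is.numeric(initial_population) || length(initial_population) != 1 ||
      !is.finite(initial_population) || initial_population < 0)
    stop("initial_population must be a single non-negative number")
  structure(list(K = as.numeric(carrying_capacity),
                 N0 = as.numeric(initial_population)),
            class = "culture_model")
}

#' @export
print.culture_model <- function(x, ...) {
  cat(sprintf("<culture_model> K = %g cells, N0 = %g cells\n", x$K, x$N0))
  invisible(x)
}

new_trajectory <- function(times, sizes) {
  stopifnot(length(times) == length(sizes))
  if (any(diff(times) <= 0)) stop("trajectory times must be strictly increasing")
  structure(data.frame(time = times, size = sizes),
            class = c("trajectory", "data.frame"))
}

#' Solve the time-varying logistic growth equation
#'
#' Population dynamics follow dN/dt = r(t) N (1 - N/K) with a piecewise-linear
#' rate r(t). This Bernoulli equation has the exact solution
#' N(t) = K / (1 + (K/N0 - 1) exp(-R(t))) with R(t) the integrated rate, which
#' is evaluated in closed form (the integrated rate of a piecewise-linear
#' curve is piecewise quadratic). The solution is exact for any sign of r,
#' handles N0 = 0 and N0 = K as fixed points, and N0 > K relaxing down to K.
#'
#' For N0 > K with a sufficiently negative integrated rate the true solution
#' diverges in finite time; such points are reported as \code{Inf} with a
#' warning.
#'
#' @param model a \code{\link{culture_model}}.
#' @param curve a \code{\link{rate_curve}}.
#' @param times sorted, non-negative times (days) at which to evaluate N(t).
#'   Time 0 is the reference at which the population equals N0.
#' @return a \code{trajectory} data frame with columns \code{time} and
#'   \code{size} (cells, real-valued).
#' @examples
#' m <- culture_model(3e6, 1e5)
#' solve_deterministic(m, rate_curve(1.0), times = 0:8)
#' @export
solve_deterministic <- function(model, curve, times) {
  stopifnot(inherits(model, "culture_model"), inherits(curve, "rate_curve"))
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be sorted strictly ascending")
  if (any(times < 0)) stop("'times' must be >= 0 (time origin is the first observation)")
  if (model$N0 == 0) return(new_trajectory(times, rep(0, length(times))))
  R <- cumulative_rate(curve, times)
  sizes <- logistic_closed_form(model$N0, model$K, R)
  if (any(!is.finite(sizes)))
    warning("population diverged (N0 > K with strongly negative rates)")
  new_trajectory(times, sizes)
}

# Stable closed form; exp(-R) under/overflow maps correctly to K and 0.
logistic_closed_form <- function(N0, K, R) {
  den <- 1 + (K / N0 - 1) * exp(-R)
  out <- K / den
  out[den <= 0] <- Inf  # finite-time blow-up branch (N0 > K, r < 0)
  out
}
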