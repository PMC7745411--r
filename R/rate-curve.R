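#' Piecewise-linear growth-rate curve
#'
#' A time-dependent per-capita growth rate r(t), represented as a piecewise
#' linear function defined by control points evenly spaced over
#' \code{[t_start, t_end]}. A single control point gives a constant rate.
#' Outside the control-point window the rate is clamped to the nearest
#' endpoint value, so that simulating or plotting slightly beyond the fitted
#' window cannot produce runaway extrapolated rates.
#'
#' Control values may be negative: the deterministic logistic solver is
#' well-behaved for negative rates. The stochastic branching simulator, whose
#' birth and death hazards must be non-negative, rejects negative values.
#'
#' @param values numeric vector of per-capita rates at the control points,
#'   in divisions/cell/day. Length >= 1.
#' @param t_start,t_end time bounds (days) over which control points are
#'   evenly spaced; the first point sits at \code{t_start}, the last at
#'   \code{t_end}. Ignored distinction for a single control point.
#' @return an object of class \code{rate_curve}.
#' @examples
#' rate_curve(0.5)                   # constant 0.5 divisions/day
#' rate_curve(c(0.2, 1.2), 0, 8)     # linear increase over 8 days
#' @export
rate_curve <- function(values, t_start = 0, t_end = t_start) {
  if (!is.numeric(values) || length(values) < 1 || !all(is.finite(values)))
    stop("'values' must be a non-empty numeric vector of finite rates")
  if (length(values) >= 2 && !(t_start < t_end))
    stop("t_start must be strictly less than t_end for >= 2 control points")
  structure(
    list(values = as.numeric(values),
         t_start = as.numeric(t_start),
         t_end = if (length(values) == 1) as.numeric(t_start) else as.numeric(t_end)),
    class = "rate_curve"
  )
}

#' @export
print.rate_curve <- function(x, ...) {
  m <- length(x$values)
  if (m == 1) {
    cat(sprintf("<rate_curve> constant r = %g /day\n", x$values))
  } else {
    cat(sprintf("<rate_curve> %d control points on [%g, %g] days\n",
                m, x$t_start, x$t_end))
    cat("  values:", paste(signif(x$values, 4), collapse = ", "), "/day\n")
  }
  invisible(x)
}

#' Control-point times of a rate curve
#'
#' @param curve a \code{\link{rate_curve}}.
#' @return numeric vector of the control-point times (days).
#' @export
control_times <- function(curve) {
  stopifnot(inherits(curve, "rate_curve"))
  m <- length(curve$values)
  if (m == 1) curve$t_start else seq(curve$t_start, curve$t_end, length.out = m)
}

#' Evaluate a rate curve
#'
#' Linear interpolation between neighbouring control points; outside
#' \code{[t_start, t_end]} the rate is clamped to the nearest endpoint value.
#'
#' @param curve a \code{\link{rate_curve}}.
#' @param t numeric vector of times (days).
#' @return per-capita rates at \code{t} (divisions/cell/day).
#' @examples
#' rate_at(rate_curve(c(0, 1), 0, 8), 4)   # 0.5
#' @export
rate_at <- function(curve, t) {
  stopifnot(inherits(curve, "rate_curve"), is.numeric(t))
  m <- length(curve$values)
  if (m == 1) return(rep.int(curve$values, length(t)))
  tt <- pmin(pmax(t, curve$t_start), curve$t_end)
  stats::approx(control_times(curve), curve$values, xout = tt)$y
}

# Precompute breakpoints, rates and exact cumulative integrals on t >= 0.
# Between consecutive breakpoints (and beyond the last) the clamped rate is
# linear, so trapezoids are exact and the cumulative is piecewise quadratic.
cum_rate_table <- function(curve) {
  kt <- control_times(curve)
  b <- c(0, kt[kt > 0])
  r <- rate_at(curve, b)
  nb <- length(b)
  C <- c(0, cumsum((r[-nb] + r[-1]) / 2 * diff(b)))
  slope <- c(if (nb > 1) diff(r) / diff(b) else numeric(0), 0)
  list(b = b, r = r, C = C, slope = slope)
}

#' Integrated growth rate
#'
#' The exact integral of the (clamped) piecewise-linear rate from the time
#' origin 0 to each requested time, i.e. the exponent in the closed-form
#' solution of the time-varying logistic equation. The antiderivative of a
#' piecewise-linear function is piecewise quadratic, so the result is exact.
#' The time origin is the first observation time of a series by convention.
#'
#' @param curve a \code{\link{rate_curve}}.
#' @param t numeric vector of times (days), all >= 0.
#' @return dimensionless cumulative rates (net log-growth in the exponential
#'   regime).
#' @examples
#' cumulative_rate(rate_curve(0.5), 4)        # 2
#' cumulative_rate(rate_curve(c(0, 1), 0, 8), 8)  # 4
#' @export
cumulative_rate <- function(curve, t) {
  stopifnot(inherits(curve, "rate_curve"), is.numeric(t))
  if (any(t < 0)) stop("cumulative_rate is defined for t >= 0")
  tab <- cum_rate_table(curve)
  cum_rate_eval(tab, t)
}

cum_rate_eval <- function(tab, t) {
  idx <- findInterval(t, tab$b)
  rt <- tab$r[idx] + tab$slope[idx] * (t - tab$b[idx])
  tab$C[idx] + (tab$r[idx] + rt) / 2 * (t - tab$b[idx])
}

# Invert the cumulative rate: smallest u >= 0 with R(u) = s (s >= 0).
# Vectorised over s; returns Inf where the level is never reached (zero tail
# rate). Used by the branching simulator's time-rescaled event clock.
cum_rate_invert <- function(tab, s) {
  nb <- length(tab$b)
  j <- findInterval(s, tab$C)  # rightmost index with C <= s: skips plateaus
  r0 <- tab$r[j]
  sl <- tab$slope[j]
  rem <- s - tab$C[j]
  lin <- abs(sl) < 1e-14
  d <- numeric(length(s))
  d[lin] <- rem[lin] / r0[lin]                 # Inf if r0 == 0 and rem > 0
  d[lin & rem == 0] <- 0
  q <- !lin
  d[q] <- (-r0[q] + sqrt(pmax(r0[q]^2 + 2 * sl[q] * rem[q], 0))) / sl[q]
  tab$b[j] + d
}
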