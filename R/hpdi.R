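#' Highest posterior density interval
#'
#' The smallest continuous interval containing a given fraction of the
#' (weighted) samples — here defaulting to 89% posterior mass. For equal
#' weights this is the minimal-width window over the sorted samples covering
#' ceiling(mass * n) of them; with weights, the minimal window whose
#' contained weight reaches \code{mass}. Width ties are broken by the lowest
#' left endpoint.
#'
#' @param samples numeric vector of posterior samples (>= 1).
#' @param mass credibility mass in (0, 1]; default 0.89.
#' @param weights optional non-negative weights (normalised internally);
#'   NULL means equal weights.
#' @return an object of class \code{hpdi}: list with \code{low}, \code{high},
#'   \code{mass}.
#' @examples
#' hpdi(1:100, mass = 0.5)  # [1, 50]
#' @export
hpdi <- function(samples, mass = 0.89, weights = NULL) {
  if (length(samples) < 1) stop("hpdi needs at least one sample")
  if (!is.numeric(mass) || mass <= 0 || mass > 1)
    stop("mass must be in (0, 1]")
  if (is.null(weights)) weights <- rep(1 / length(samples), length(samples))
  if (length(weights) != length(samples) || any(weights < 0))
    stop("weights must be non-negative and match samples in length")
  weights <- weights / sum(weights)
  ord <- order(samples)
  x <- samples[ord]
  w <- weights[ord]
  n <- length(x)
  # two-pointer sweep over cumulative-weight windows; for equal weights this
  # reduces to windows of ceiling(mass * n) samples (up to float rounding)
  best_lo <- x[1]; best_hi <- x[n]; best_w <- Inf
  j <- 1L
  acc <- w[1]
  tol <- 1e-12
  for (i in seq_len(n)) {
    while (acc < mass - tol && j < n) {
      j <- j + 1L
      acc <- acc + w[j]
    }
    if (acc < mass - tol) break
    width <- x[j] - x[i]
    if (width < best_w - tol) {
      best_w <- width; best_lo <- x[i]; best_hi <- x[j]
    }
    acc <- acc - w[i]
  }
  structure(list(low = best_lo, high = best_hi, mass = mass), class = "hpdi")
}

#' @export
print.hpdi <- function(x, ...) {
  cat(sprintf("%.0f%% HPDI: [%g, %g]\n", 100 * x$mass, x$low, x$high))
  invisible(x)
}
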