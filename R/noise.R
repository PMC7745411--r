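#' Sampling scheme for cell counting
#'
#' The ordered fractions of cells carried from one sampling stage to the
#' next. For haemocytometer counting of a 1 mL culture this is typically two
#' stages: the pipetted sample (e.g. 10 uL of 1 mL = 0.01) and the counted
#' chamber volume as a fraction of that sample (e.g. 0.2 uL of 10 uL = 0.02).
#' A 1:1 dye dilution does not change the number of cells in the sample and
#' is folded into the second fraction by the user.
#'
#' @param fractions numeric vector of fractions, each in (0, 1], non-empty.
#' @return an object of class \code{sampling_scheme}.
#' @export
sampling_scheme <- function(fractions) {
  if (!is.numeric(fractions) || length(fractions) < 1 ||
      any(fractions <= 0) || any(fractions > 1))
    stop("fractions must be a non-empty numeric vector with values in (0, 1]")
  structure(list(fractions = as.numeric(fractions)), class = "sampling_scheme")
}

#' Counting-noise specification
#'
#' Post-sampling miscounting error. \code{normal_binomial} assumes each
#' individual cell in the counted sample is miscounted with probability
#' \code{p_wrong}, approximated by zero-mean Gaussian noise with the binomial
#' standard deviation sqrt(c p (1-p)); the noisy count is rounded to the
#' nearest integer and floored at zero. \code{none} disables the stage.
#' Counting noise is a pluggable filter so that different instruments'
#' error models can be swapped in.
#'
#' @param kind \code{"normal_binomial"} or \code{"none"}.
#' @param p_wrong probability a single cell is miscounted, in [0, 1).
#' @return an object of class \code{counting_noise}.
#' @export
counting_noise <- function(kind = c("normal_binomial", "none"), p_wrong = 0.05) {
  kind <- match.arg(kind)
  if (!is.numeric(p_wrong) || p_wrong < 0 || p_wrong >= 1)
    stop("p_wrong must be in [0, 1)")
  structure(list(kind = kind, p_wrong = as.numeric(p_wrong)),
            class = "counting_noise")
}

#' Simulate an observed cell count
#'
#' The forward observation model: a well-dispersed sample contains a
#' Poisson-distributed number of cells, so successive sampling stages form a
#' nested series of Poisson draws, c_i ~ Poisson(c_{i-1} f_i) starting from
#' the true population. Poisson sampling alone underestimates real counting
#' error, so a counting-noise filter is applied afterwards.
#'
#' @param n_true true population size(s), cells, >= 0. Vectorised.
#' @param scheme a \code{\link{sampling_scheme}}.
#' @param noise a \code{\link{counting_noise}}; default none.
#' @return simulated non-negative integer count(s), one per \code{n_true}.
#' @export
simulate_observation <- function(n_true, scheme,
                                 noise = counting_noise("none")) {
  stopifnot(inherits(scheme, "sampling_scheme"), inherits(noise, "counting_noise"))
  if (any(n_true < 0)) stop("n_true must be >= 0")
  cnt <- n_true
  for (f in scheme$fractions) cnt <- stats::rpois(length(cnt), cnt * f)
  apply_counting_noise(cnt, noise)
}

apply_counting_noise <- function(cnt, noise) {
  if (noise$kind == "normal_binomial" && noise$p_wrong > 0) {
    sdv <- sqrt(cnt * noise$p_wrong * (1 - noise$p_wrong))
    cnt <- pmax(0, round(cnt + stats::rnorm(length(cnt), 0, sdv)))
  }
  as.numeric(cnt)
}

#' Expected observed count
#'
#' Mean of the nested-Poisson observation chain: the true population times
#' the product of the sampling fractions. Counting noise has zero mean and
#' does not contribute.
#'
#' @param n_true true population size(s), cells, >= 0.
#' @param scheme a \code{\link{sampling_scheme}}.
#' @return expected count(s), real-valued.
#' @examples
#' expected_count(95000, sampling_scheme(c(0.01, 0.02)))  # 19
#' @export
expected_count <- function(n_true, scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (any(n_true < 0)) stop("n_true must be >= 0")
  n_true * prod(scheme$fractions)
}

#' Point estimate of the population from one count
#'
#' Inverts the expected-count relation: count divided by the product of the
#' sampling fractions. Used to place observed counts on population axes and
#' to centre the N0 prior.
#'
#' @param count observed count(s), >= 0.
#' @param scheme a \code{\link{sampling_scheme}}.
#' @return estimated population size(s), cells (real-valued).
#' @examples
#' point_estimate_population(19, sampling_scheme(c(0.01, 0.02)))  # 95000
#' @export
point_estimate_population <- function(count, scheme) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  p <- prod(scheme$fractions)
  if (p <= 0) stop("product of sampling fractions must be > 0")
  count / p
}

#' Sampling fractions from haemocytometer volume bookkeeping
#'
#' Converts the pipetting volumes of a typical haemocytometer workflow into
#' the two sampling fractions the count table expects. A sample of
#' \code{sample_volume} is taken from \code{culture_volume}; it is mixed with
#' dye at \code{dilution}:1 total:sample ratio (1:1 mixing gives 2), and
#' \code{counted_volume} of the diluted mixture is counted. The dilution does
#' not change the number of cells in the sample, so the counted volume is
#' re-expressed in undiluted terms: counted_volume / dilution.
#'
#' @param culture_volume total culture volume (same units throughout, e.g. uL).
#' @param sample_volume volume pipetted from the culture.
#' @param counted_volume chamber volume actually counted (diluted mixture).
#' @param dilution fold-dilution of the sample before counting (2 = 1:1 dye).
#' @return named numeric vector \code{c(sample1, sample2)}.
#' @examples
#' haemocytometer_fractions(1000, 10, 0.4, dilution = 2)  # 0.01, 0.02
#' @export
haemocytometer_fractions <- function(culture_volume, sample_volume,
                                     counted_volume, dilution = 2) {
  stopifnot(culture_volume > 0, sample_volume > 0, counted_volume > 0,
            dilution >= 1)
  c(sample1 = sample_volume / culture_volume,
    sample2 = (counted_volume / dilution) / sample_volume)
}

#' Growth rate under inhibition
#'
#' Standard hyperbolic (Hill) dose-response for the per-capita growth rate:
#' r(c) = r_max / (1 + (c / ic50)^hill). At c = ic50 the rate is half-maximal
#' by definition. Useful for sanity-checking inferred rates against known
#' inhibitor potencies.
#'
#' @param r_max uninhibited growth rate (divisions/day).
#' @param conc inhibitor concentration (same units as \code{ic50}).
#' @param ic50 half-maximal inhibitory concentration.
#' @param hill Hill coefficient (default 1).
#' @return predicted growth rate(s).
#' @examples
#' inhibited_rate(1.0, 240, 240)  # 0.5
#' @export
inhibited_rate <- function(r_max, conc, ic50, hill = 1) {
  stopifnot(ic50 > 0, all(conc >= 0))
  r_max / (1 + (conc / ic50)^hill)
}
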