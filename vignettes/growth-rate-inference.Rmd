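---
title: "Inferring time-varying growth rates from cell counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring time-varying growth rates from cell counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellrate)
```

## The problem

Suspension cell cultures are routinely monitored by counting a tiny sample
of the culture — often under 10 µL on a haemocytometer. Those counts are
cheap, non-destructive, and collected anyway; but turning them into a
*growth rate over time* is not straightforward. The common summary, the
population doubling time, is only defined under exponential growth, and a
culture approaching its carrying capacity, adapting to a drug, or recovering
from overgrowth is exactly the situation where the rate changes and the
summary breaks down.

`cellrate` assumes logistic growth with a time-dependent per-capita rate and
infers that rate, with calibrated uncertainty, from a handful of noisy
counts. The carrying capacity K must be known beforehand — it is a property
of the cell line and culture volume, usually well characterised — and in
exchange the rate r(t) is free to change.

## Growth model

The population follows

$$\frac{dN}{dt} = r(t)\,N\left(1 - \frac{N}{K}\right)$$

with r(t) piecewise linear, defined by 1–3 control points evenly spaced over
the observation window (time 0 is the first observation). One control point
is a constant rate; two, a linear trend; three, a broken stick with a
central breakpoint. This deliberately rigid parameterisation resists
overfitting sparse count timelines. Outside the window the rate is clamped
to its endpoint value, so that evaluating or simulating slightly beyond the
data cannot extrapolate to runaway rates; the data say nothing about the
rate out there, and a constant continuation is the most conservative choice.

Because r(t) is piecewise linear, its integral R(t) is piecewise quadratic
and exact. The Bernoulli equation above then has the closed-form solution

$$N(t) = \frac{K}{1 + (K/N_0 - 1)\,e^{-R(t)}}$$

which `solve_deterministic()` evaluates directly: the usual outer quadrature
disappears because $\int_0^t (r/K)e^{R} \, d\zeta = (e^{R(t)}-1)/K$. The
solver is therefore exact to floating point, costs microseconds (which
matters inside the ABC loop, where it runs tens of thousands of times per
fit), behaves correctly for negative rates, and has N = 0 and N = K as exact
fixed points. Adaptive ODE integration of the differential form (via
`deSolve::lsoda`) is retained in the test suite as an independent
cross-check; the two agree to relative error below 1e−5 on randomised
instances. An overgrown culture (N0 > K) with a strongly negative rate
diverges in finite time — a property of the equation, not the
implementation — and is reported as `Inf` with a warning.

Units throughout: time in days, rates in divisions/cell/day, populations in
cells.

## Stochastic simulator

For small populations, demographic noise matters. The logistic branching
process models cells as particles with birth hazard λ = N·r(t) and
density-dependent death hazard μ = N(N−1)·r(t)/K, whose mean dynamics are
logistic. `simulate_branching()` is exact and event-driven: between events N
is constant, so the total hazard factorises as a(N)·r(t) with
a(N) = N + N(N−1)/K, and the whole simulation can run on the transformed
clock s = R(t), where inter-event gaps are exponential with rate a(N).
Event times are mapped back to real time by inverting the piecewise-quadratic
R analytically (per-segment quadratic formula; plateaus where r = 0 are
skipped exactly). This treats the time-dependence of the hazards exactly
rather than freezing them between events, at no extra cost. The split into
birth or death does not depend on t, which is what makes the rescaling
exact.

On the stochastic path all control values must be non-negative — λ and μ are
hazards — while the deterministic solver accepts negative rates. Ensembles
derive per-replicate seeds deterministically from one user seed, so results
are reproducible and independent of evaluation order. The simulator is
practical below roughly 2·10⁶ cells; every division and death is an explicit
event, so cost scales with K.

## Observation model

Counting a well-mixed culture is modelled in two stages:

* **Sampling noise.** A sample holds a Poisson-distributed number of cells,
  so successive sampling steps form a nested chain
  $c_i \sim \mathrm{Poisson}(c_{i-1} f_i)$ starting at the true population.
  Nested Poisson thinning is distributionally identical to a single Poisson
  with the product rate — a property the test suite verifies by a
  goodness-of-fit comparison — so the per-step fractions only need to be
  right in product; recording them per step simply mirrors how pipetting is
  documented. A 1:1 dye dilution does not change the number of cells in the
  sample and is folded into the second fraction (0.4 µL counted at 1:1 is
  0.2 µL undiluted; 0.2/10 µL = 0.02).
* **Counting noise.** Poisson sampling alone is known to understate real
  counting error. The default filter assumes each cell in the chamber is
  miscounted with probability `p_wrong = 0.05` and applies the Gaussian
  approximation of that binomial, rounding to the nearest integer and
  flooring at zero (counts are non-negative integers; the distributional
  family says nothing about discretisation, so round-then-floor is our
  choice). The filter is pluggable (`counting_noise(kind = ...)`) because
  different instruments warrant different error models; `none` and
  `normal_binomial` ship.

## Inference

The forward model — growth curve, nested Poisson sampling at the observed
times and fractions, counting noise — is inverted with ABC-SMC:

* **Priors.** Uniform on each control point over a user range (default 0.01
  to 3.0 divisions/day, wide enough for mammalian suspension lines). The
  initial population is latent with a uniform prior spanning 0.2–5 times the
  first observation's point estimate: the point estimate is unbiased but
  highly dispersed at small counts, and this range comfortably covers its
  sampling distribution without letting N0 absorb the early-time rate
  signal. Control-point counts {1, 2, 3} compete as models under a uniform
  model prior; per-model posterior mass is reported rather than silently
  picking a winner.
* **Distance.** Euclidean distance between square-root-transformed counts.
  The square root stabilises Poisson variance, so early small counts and
  late large counts contribute comparably; plain Euclidean is selectable.
* **Schedule.** Generation 1 samples the prior. Each later generation
  accepts particles at distance ≤ ε, where ε is the `epsilon_quantile` of
  the previous generation's accepted distances — non-increasing by
  construction. The default quantile is 0.25: the distance is stochastic
  (the forward model re-draws observation noise every evaluation), which
  puts a noise floor of order 1 on the sqrt-count scale under typical
  haemocytometer settings, and a 0.25 quantile reaches that floor within
  about six generations. A 0.5 quantile needs roughly ten generations for
  the same threshold — with fewer it leaves visibly inflated posteriors —
  while quantiles near 0.1 can chase the threshold below the noise floor and
  stall acceptance. Both the quantile and the generation budget are
  configuration, not constants.
* **Kernel and weights.** Component-wise Gaussian perturbation with standard
  deviation $\sqrt{2\,\widehat{\mathrm{Var}}}$ per component from the
  previous generation of the same model (the standard adaptive choice);
  proposals outside the prior box are rejected and redrawn. Importance
  weights are prior density over the weighted kernel mixture within the
  particle's model, normalised across all particles, so the per-model weight
  sums are the model probabilities. A generation that cannot fill its quota
  within 500 × n_particles attempts aborts with a diagnostic: the ε schedule
  was too aggressive for the data.
* **Grouping.** Series in one group share the rate curve but keep
  independent N0 parameters — matching replicate wells seeded separately
  from one line. Whether replicates should also share N0 is genuinely
  ambiguous; independent N0 is the weaker and safer assumption.
* **Parallelism.** The config accepts a worker count for compatibility, but
  execution is sequential: at these problem sizes a fit takes seconds, and a
  single RNG stream makes results bit-reproducible and trivially independent
  of worker count.

Identical seed and configuration give an identical posterior.

## Reporting

Credible intervals are **highest posterior density intervals**: the smallest
continuous interval containing the stated mass, 89% by default. For weighted
samples the implementation sweeps cumulative-weight windows over the sorted
samples (equal weights reduce to the minimal window covering ⌈0.89 n⌉ of
them); width ties are broken by the leftmost window. A brute-force window
search is the test oracle. 89% is deliberately not 95%: with a few hundred
posterior samples the tails of a 95% interval are unstable, and the
convention signals that the bound is descriptive, not a significance test.

`fit_table()` writes one row per (group, model, parameter) with weighted
mean, median and HPDI; `plot_report()` draws the two standard panels —
counts as population estimates over the posterior population band, and the
rate curve with dashed HPDI bounds plus a raincloud (kernel density,
quartile box, jittered weighted samples) per control point of the most
probable model. Every number behind the figure is available from
`report_panels()` so tests check content, not pixels.

## Synthetic data

`builtin_scenarios()` defines the three reference cases used for validation:
constant r = 1.0, increasing 0.2 → 1.2 and decreasing 1.2 → 0.2
divisions/day over 8 days, with K = 3·10⁶, N0 = 9.5·10⁴, counts every second
day, fractions 0.01 × 0.02 and 5% miscount noise — the regime of the worked
example, where day-0 counts are in the tens. The truth values themselves are
this package's choices, placed inside the default prior. The generator
reproduces sampling and counting noise but not everything real cultures do:
no nutrient depletion beyond the logistic form, no death/birth separation,
no mis-estimated K, no day-to-day handling effects. Passing recovery tests
therefore demonstrates that the inference machinery is correct and
well-calibrated under its own assumptions, not that the logistic form fits
any particular cell line.

One edge is worth noting: `simulate_observation()` always draws the nested
Poisson chain, including at fraction 1.0 (a sample of the whole culture is
still a Poisson count in this model), but `generate_scenario()` treats the
combination "all fractions 1 and no counting noise" as an exact census and
returns the rounded deterministic curve — that combination exists only to
express the noiseless limit.

## Validation problem sizes

The shipped test suite and `scripts/acceptance.R` validate at sizes chosen
to exercise the method meaningfully on a single core: 500 branching
replicates for the stochastic/deterministic comparison (K = 10⁴, N0 = 100,
r = 0.7/day); 20 repetitions each for constant-rate coverage and trend-sign
recovery with 200 particles over 6 generations; 10 repetitions for the
detectability bracket, which checks that two cultures whose constant rates
differ by 50% yield disjoint 89% HPDIs while a 10% difference does not —
bracketing the practical resolution of the method at roughly a 20% rate
change under this sampling design.

## Limitations

K is an input, not inferred; a mis-specified K biases late-time rates (an
overestimated K makes a saturating culture look like its rate is falling).
Rates near saturation are weakly identified in principle — at N = K the rate
has no observable effect — so endpoint HPDIs widen, and experiments should
put counts in the growth phase. The death rate and carrying capacity are
assumed constant; only the growth rate moves. More than three control points
are configurable but invite overfitting on typical 5–10-point timelines.
ABC posteriors are approximate by construction: the acceptance threshold
ends at the observation-noise floor, not zero, so intervals are slightly
conservative.
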