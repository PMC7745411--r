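# cellrate

Infer a **time-dependent population growth rate** in suspension cell cultures
from nothing but sparse, noisy cell counts.

During sustained culture experiments the growth rate is rarely constant:
cells adapt to drugs, recover from overgrowth, or compete for nutrients. End
point measures such as the population doubling time assume exponential
growth and cannot track these changes. `cellrate` treats the per-capita rate
as a function of time and infers it, with honest uncertainty, from the
counts a lab collects anyway for monitoring.

## Model

The population N(t) follows logistic growth with carrying capacity K and a
time-varying rate r(t), represented as a piecewise-linear function with 1–3
evenly spaced control points:

    dN/dt = r(t) N (1 − N/K)

This Bernoulli equation has the exact solution

    N(t) = K / (1 + (K/N0 − 1) exp(−R(t))),   R(t) = ∫₀ᵗ r(ξ) dξ

where R(t) is available in closed form because r(t) is piecewise linear.
Alternatively, a stochastic logistic branching process (birth hazard
λ = N·r(t), density-dependent death hazard μ = N(N−1)·r(t)/K) simulates the
culture as individual cells; it is exact, event-driven, and recommended for
populations below ~2·10⁶ cells.

Observations are modelled in two stages: **sampling noise** — each sampling
step carries a Poisson-distributed number of cells, so multi-step sampling is
a nested series of Poisson draws — and **counting noise** — a per-cell
miscount probability (default 5%) applied as its Gaussian approximation.
This forward model is inverted by **ABC-SMC** (approximate Bayesian
computation with sequential Monte Carlo): uniform priors on the rate control
points, a shrinking acceptance threshold on a variance-stabilised distance
between observed and simulated counts, and model comparison across 1/2/3
control points under a uniform model prior. Results are reported as weighted
posterior samples and **89% highest posterior density intervals** (the
smallest continuous interval holding 89% of the posterior mass).

## Worked example

Five haemocytometer counts of one culture over 8 days. Each count took a
10 µL sample of the 1 mL culture (fraction 0.01), mixed 1:1 with trypan
blue, and counted 0.4 µL of the mixture — 0.2 µL of undiluted sample, i.e.
a fraction 0.02 of the sample:

```
name,time,count,sample1,sample2
minimal,0.0,19,0.01,0.02
minimal,2.0,105,0.01,0.02
minimal,4.0,403,0.01,0.02
minimal,6.0,529,0.01,0.02
minimal,8.0,591,0.01,0.02
```

with a TOML config that only needs the carrying capacity:

```toml
carrying_capacity = 3e6
```

Both files ship with the package under `inst/extdata/`:

```r
library(cellrate)
csv <- system.file("extdata", "minimal.csv", package = "cellrate")
toml <- system.file("extdata", "minimal.toml", package = "cellrate")
res <- cmd_fit(csv, toml, out_dir = "results", seed = 42)
read.csv("results/minimal.fit.csv")
```

writes `results/minimal.fit.csv` and `results/minimal.pdf` and prints (rates
in divisions/cell/day, populations in cells):

```
    group model  parameter time         mean       median     hpdi_low    hpdi_high model_probability
1 minimal     1 n0:minimal   NA 8.776251e+04 8.768504e+04 5.834192e+04 1.173909e+05         0.3937466
2 minimal     1         r1    0 1.046532e+00 1.041743e+00 8.956003e-01 1.167451e+00         0.3937466
3 minimal     2 n0:minimal   NA 8.914163e+04 8.867565e+04 4.907527e+04 1.204826e+05         0.3639684
4 minimal     2         r1    0 9.962614e-01 9.495694e-01 7.049807e-01 1.470597e+00         0.3639684
5 minimal     2         r2    8 1.183371e+00 1.276446e+00 2.826051e-01 1.791770e+00         0.3639684
...
```

Reading this: under the constant-rate model the culture grew at about 1.05
divisions per cell per day (89% HPDI 0.90–1.17), starting from about
8.8 × 10⁴ cells — consistent with the naive point estimate
19 / (0.01 × 0.02) = 95,000 cells. No single control-point count dominates
the model probabilities (0.39 / 0.36 / 0.24): with five noisy counts a
constant and a trending rate describe these data about equally well. The figure shows the counts as
population estimates over the posterior population band (top) and the
inferred rate curve with its 89% HPDI and a raincloud of posterior samples
per control point (bottom).

Synthetic benchmark data with known truth come from the built-in scenarios:

```r
cmd_simulate("increasing", out_path = "increasing.csv", seed = 3)
```

A thin command-line wrapper is installed at `inst/cli/cellrate`:

```sh
Rscript inst/cli/cellrate fit minimal.csv minimal.toml --out results --seed 42
Rscript inst/cli/cellrate simulate constant --seed 1 --out constant.csv
```

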