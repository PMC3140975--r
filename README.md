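# dropenc

Statistical design, simulation and estimation for **single-target-cell
encapsulation in nanoliter droplets**.

Drop-on-demand ejectors print droplets from a reservoir holding a mixed
suspension of target and non-target cells onto a grid (typically 10 × 10).
Which cells land in which droplet is random, so isolating droplets that hold
*exactly one target cell* is a statistical problem, not a deterministic one.
This package is for experimenters and modelers who need to (i) decide how
many droplets to inspect, (ii) choose loading concentration and droplet
volume, and (iii) validate count data against the underlying probability
model.

## The model

One printed array of *n* droplets is described by four random variables:

| Variable | Meaning | Law |
|---|---|---|
| X_d | droplet contains ≥ 1 cell | Bernoulli(p_occ), occupied count ~ Binomial(n, p_occ) |
| X_c | cells per droplet | Poisson(λ), λ = C·V |
| X_t | target cells per droplet | Poisson(λF) (thinned) |
| X_s | exactly one target cell | combined law below |

with C the loading concentration, V the droplet volume and F the target
fraction. The combined single-target law is

```
P(X_s = 1) = p_occ · λ_t e^(−λ_t),   λ_t = λF,   p_occ = 1 − e^(−λ),
```

bounded above by e⁻¹ ≈ 36.8% at λ_t = 1. Array sizing uses Chebyshev's
inequality: requiring P(|k/n − p| ≥ ε) ≤ α gives

```
n_min = p(1 − p) / (α ε²)
```

droplets at tolerance ε and confidence 1 − α. Design equations
V_min = V_cell/f and C_max = 1/V link cell volume, volume fraction f,
droplet volume and concentration. A seeded Monte Carlo simulator
(Poisson loading + binomial thinning) generates droplet arrays for
validation and power studies, and estimators recover λ with normal, score
or exact (Garwood) intervals.

## Worked example

```r
library(dropenc)

# How many droplets must be inspected at 15% tolerance, 90% confidence,
# if about 60% of droplets are occupied?
sampling_design(0.6, 0.15, 0.10)
#> Chebyshev/LLN sampling design
#>   p = 0.6, tolerance = 0.15, confidence = 0.9
#>   n_min = 107 droplets (deviation bound 0.0997 at n_min)

# Physical design: minimum droplet volume at 1.7% cell volume fraction,
# and the concentration giving one expected cell in that droplet
min_droplet_volume(0.5236, 0.017)   # 30.8  (pl)
max_cell_concentration(30.8)        # 3.25e7 (cells/ml)

# Simulate one 10x10 array at 1e5 cells/ml, 10% targets, and analyze it
run_pipeline(list(seed = 42))
#> dropenc pipeline report (v0.1.0, seed 42)
#>   lambda = 0.77, occupancy model 0.537, observed p_d_hat 0.570
#>   lambda_hat = 0.85 [0.6693, 1.031] (normal)
#>   single-target: empirical 9.00% vs combined law 3.83%
#>   sampling design: n_min = 107 at p = 0.6, tol 0.15, conf 0.9
```

Reading the report: 100 droplets of 7.7 nl at 1.0 × 10⁵ cells/ml give a
Poisson loading rate λ = 0.77, predicting 53.7% occupancy; the simulated
array observed 57%. The rate estimate 0.85 brackets the truth. The
single-target line shows the combined law (3.8%) against the observed
singlet rate (9%): the combined law is a lower-bound-style approximation
away from saturated occupancy — see the methods vignette
(`vignettes/encapsulation-statistics.Rmd`) for why, and for every other
modeling decision.

Saturation of encapsulation probability with concentration:

```r
fit_saturation_curve(c(0.5, 1, 1.5, 2), c(27.1, 58.3, 76.8, 87.3))
#> Saturation fit P(C) = a(1 - exp(-bC)): a = 138.8%, b = 0.514 per 1e5 cells/ml
#>   R^2 = 0.9839 (adjusted 0.9518), 4 points
```

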