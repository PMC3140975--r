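---
title: "Statistical design of single-target-cell encapsulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical design of single-target-cell encapsulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropenc)
```

## The process being modeled

A drop-on-demand ejector draws from a reservoir holding a heterogeneous
suspension of target and non-target cells and places nanoliter droplets on a
grid (typically 10 × 10). Because the droplet volume is much larger than a
cell, which cells end up in which droplet is random. Four random variables
describe one printed array:

* **X_d** — whether a droplet contains any cell ("occupancy"; a Bernoulli
  success, so the number of occupied droplets among *n* is binomial);
* **X_c** — the number of cells in a droplet. Each of the vast number of
  cells in the reservoir independently has a tiny chance of landing in a
  given droplet, so X_c is Poisson with rate λ = C·V (loading concentration
  × droplet volume; 1.0 × 10⁵ cells/ml in 7.7 nl droplets gives λ = 0.77);
* **X_t** — the number of *target* cells in a droplet. If a fraction F of
  the suspension is the target type and each encapsulated cell is a target
  independently with probability F, X_t is the thinned Poisson with rate λF;
* **X_s** — the indicator that a droplet holds exactly one target cell, the
  event the experiment is designed to produce.

The combined single-target law multiplies occupancy by the single-target
Poisson term:

P(X_s = 1) = p_occ · λ_t e^(−λ_t),  P(X_s = 0) = 1 − P(X_s = 1),

with p_occ = 1 − e^(−λ) under Poisson loading. Since λ_t e^(−λ_t) ≤ e^(−1),
no design can push the single-target rate above ≈ 36.8%, attained at
λ_t = 1.

### A deliberate caveat about the combined law

Under the generative model actually simulated here (X_c ~ Poisson(λ),
X_t | X_c ~ Binomial(X_c, F)), the *marginal* probability of exactly one
target is λF·e^(−λF) with no occupancy factor — a droplet containing a
target is automatically occupied, so multiplying by p_occ discounts empty
droplets a second time. The factorized law is therefore exact only in the
limit p_occ → 1 and undershoots at moderate loading rates (at λ = 0.77,
F = 0.5 the gap is ≈ 12 percentage points). `single_target_model_check()`
reports both numbers and their gap rather than hiding the approximation;
the test suite pins the gap to its closed form and verifies sub-point
agreement in the near-saturated regime (λ = 5). When occupancy is estimated
empirically rather than modeled, the `occupancy_override` simulator
parameter reproduces a measured p_occ while keeping the conditional count
law (zero-truncated Poisson) intact — the minimal departure from pure
Poisson loading that can match an observed empty-droplet rate.

## How many droplets must be inspected?

Counting statistics on the array only speak for the reservoir if the array
is large enough for the law of large numbers. Chebyshev's inequality bounds
the deviation of the observed occupancy proportion k/n from p:

P(|k/n − p| ≥ ε) ≤ p(1 − p)/(n ε²),

and inverting it at significance α gives the minimum array size
n_min = p(1 − p)/(α ε²). The package rounds to the nearest integer, which
reproduces the standard worked values at ε = 0.15, 1 − α = 0.90 — 107
droplets at p = 0.6, 50 at p = 0.87, 108 at p = 0.58 — and 111 at the worst
case p = 0.5; a `ceiling = TRUE` mode (107/51/109/112) is available for
strictly conservative sizing. (Worked accounts of this rule sometimes quote
"100 droplets" for the p = 0.5 worst case; the formula gives 111, and this
package reports the formula's value. A 10 × 10 array is nonetheless
adequate in practice because Chebyshev is loose: at n = 100 and p = 0.6 the
empirical coverage of the ±15% band is far above 90%, which the test suite
measures by simulation.)

```{r sample-size}
sampling_design(0.6, 0.15, 0.10)
sampling_fraction(100, 7.6, 0.1)  # % of a 0.1 ml reservoir used by 100 droplets
```

## Physical design equations

Two algebraic levers connect the statistics to the hardware:

* **Minimum droplet volume.** Keeping a cell at or below a volume fraction
  f of its droplet requires V ≥ V_cell/f. The default cell volume is
  0.5236 pl — a 10 µm diameter sphere; this is an *inferred, configurable*
  default (single-cell volume is rarely printed alongside encapsulation
  data), and with f = 1.7% it gives a 30.8 pl minimum droplet.
* **Maximum loading concentration.** One expected cell per droplet of
  volume V means C_max = 1/V; for 30.8 pl, C_max = 32.5 × 10⁶ cells/ml.

Encapsulation probability versus concentration saturates; the package fits
P(C) = a(1 − e^(−bC)) by Levenberg–Marquardt least squares with fixed
deterministic starting values (a₀ = 1.5·max P, b₀ = 0.5), tolerance 1e−10,
and a 500-iteration cap. The functional form is an assumption: published
fits of this shape rarely state the model explicitly, and on the canonical
four-point data set (27.1/58.3/76.8/87.3% at 0.5–2.0 × 10⁵ cells/ml) this
form yields a = 138.8, b = 0.514, R² = 0.984 — close to, but not exactly,
the coefficient pair often quoted with those points (a = 131, b = 0.558,
R² = 0.995), whose regression specification is not recoverable. The test
suite therefore gates agreement with an independent brute-force (a, b) grid
search and exact-model recovery on noiseless curves, not the historical
coefficients. Both plain and adjusted R² are reported.

Two volume-fraction conventions circulate (single-cell over droplet volume
vs expected total cell volume over droplet volume); they disagree by a
factor of λ and published figures cannot always be reconciled with either.
`volume_fraction()` implements both and documents which is which.

```{r design}
min_droplet_volume(0.5236, 0.017)
max_cell_concentration(30.8)
fit_saturation_curve(c(0.5, 1, 1.5, 2), c(27.1, 58.3, 76.8, 87.3))
```

## The simulator

`simulate_droplet_array()` embodies the generative model: per droplet,
`total_cells ~ Poisson(λ)` and `target_cells | total ~ Binomial(total, F)`,
independent across droplets, on a row-major 0-based grid. Independence
across droplets and a binary target/non-target mixture are assumptions
carried over from the model: cell settling, aggregation, droplet-volume
jitter and >2 cell classes are deliberately *not* simulated, so passing
tests validate the model layer, not those real-world effects. Randomness is
R's default Mersenne-Twister seeded once per array; replicate experiments
draw per-replicate substream seeds in a single deterministic block, so any
replicate is reproducible in isolation and identical designs give
byte-identical CSV output.

## Estimation and the recovery study

The loading-rate MLE is the sample mean of per-droplet counts. Three
confidence intervals are offered:

* `"normal"` (default, matching the usual CLT presentation):
  λ̂ ± z·√(λ̂/n), truncated at zero;
* `"score"`: inverts (λ̂ − λ)² ≤ z²λ/n;
* `"exact"`: Garwood chi-square, guaranteed conservative.

`recovery_study()` defaults to the **score** interval, and this is a
deliberate deviation from the normal default. The choice is analytic, not
empirical: with n = 100 droplets and λ = 0.03 (the low end of the tabulated
λ ∈ [0.03, 0.95] range), the array's total count is Poisson with mean 3,
and enumerating that law shows the Wald interval covers only ≈ 80% while
Garwood covers ≈ 98.8%; the score interval covers ≈ 96.7% at λ = 0.03 and
≈ 94–95% across the rest of the range, the only one of the three inside a
reasonable [0.92, 0.98] band everywhere. The study simulates a full
factorial (λ, F) grid, 2000 replicates of 100 droplets per cell in the
acceptance suite (≈ seconds of CPU), and reports per-cell bias, its
standard error, z-scores and interval coverage. Because the estimator is
exactly unbiased, per-cell z-scores are standard normal; the suite checks
them at 2 SE at the grid's λ endpoints and with a joint chi-square across
the full grid (a marginal 2-SE band applied to many cells simultaneously
would fail by chance in a third of runs).

`lln_demonstration()` backs the sample-size story without any sampling: it
enumerates the exact Kolmogorov–Smirnov distance between the binomial
occupancy proportion and its normal approximation, which falls
monotonically from n = 10 to n = 100 at both p = 0.583 and p = 0.873.

```{r estimation}
rep <- run_pipeline(list(seed = 42))
rep
lln_demonstration(0.583)
```

## Numerical choices

* Binomial PMF: direct product for n ≤ 50 (bit-comparable with naive
  evaluation), log-space assembly above (lchoose + log powers) to avoid
  factorial overflow; degenerate p ∈ {0, 1} short-circuits exactly.
* Stirling approximation: √(2πn)(n/e)ⁿ, with 0! returned as exactly 1 by
  convention (the approximation has no value at zero); inside the binomial
  coefficient the boundary factorials k ∈ {0, n} fall back to the exact
  PMF. Relative error obeys the classical Robbins bracket
  1/(12n+1) < err < 1/(12n), dropping below 0.5% by n = 20.
* Poisson normalization tests truncate the support at the smallest k with
  cumulative mass above 1 − 1e−12.
* Zero-truncated Poisson sampling uses rejection (acceptance probability
  1 − e^(−λ)); adequate at the λ ≤ a-few regime this tool targets.
* Reports serialize with stable key order and 12-significant-digit floats
  so reproducibility is byte-testable.

## Problem sizes used in the test suite

Simulation-backed assertions use 10⁵-droplet arrays for law checks (3-SE
bands), 10⁴ Chebyshev replicates, and 2000 × 100-droplet replicates per
recovery-study cell — sizes at which Monte Carlo error is far below every
asserted tolerance while the whole suite runs in well under a minute.

## Limitations

* The combined single-target law is an approximation away from saturated
  occupancy (see above); the package reports its gap instead of forcing
  agreement.
* Experimental effects (settling, aggregation, droplet-size dispersion,
  ejection bias) are out of scope; an observed occupancy can be matched via
  `occupancy_override`, but the cause of a gap between observed occupancy
  and 1 − e^(−λ) cannot be diagnosed from counts alone.
* The saturation-curve functional form is assumed, and historical
  coefficient pairs for it are not treated as ground truth.
* Raw per-droplet experimental tables for the canonical data sets were
  never published; all validation is against closed forms and the package's
  own simulator.
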