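#' Chebyshev bound on the deviation of an observed proportion
#'
#' For `n` Bernoulli trials with success probability `p`, Chebyshev's
#' inequality bounds the chance that the observed proportion `k/n` deviates
#' from `p` by at least `eps`:
#' \deqn{P(|k/n - p| \ge \varepsilon) \le \frac{p(1-p)}{n\varepsilon^2},}
#' capped at 1. The bound is distribution-free and conservative; the actual
#' deviation probability of a binomial proportion is usually far smaller.
#'
#' @param n Positive integer number of trials (droplets inspected).
#' @param p Success probability in \[0, 1\].
#' @param eps Tolerance, strictly positive.
#' @return Upper bound on the deviation probability, in \[0, 1\].
#' @examples
#' chebyshev_deviation_bound(107, 0.6, 0.15)  # just under 0.10
#' @export
chebyshev_deviation_bound <- function(n, p, eps) {
  if (any(n < 1) || any(n != round(n))) stop("`n` must be a positive integer")
  if (any(p < 0) || any(p > 1)) stop("`p` must be a probability in [0, 1]")
  if (any(!is.finite(eps)) || any(eps <= 0)) {
    stop("`eps` must be strictly positive, got ", eps[eps <= 0][1L])
  }
  pmin(1, p * (1 - p) / (n * eps^2))
}

#' Minimum sample size from the Chebyshev/LLN rule
#'
#' Inverts the Chebyshev bound: requiring
#' \eqn{P(|k/n - p| \ge \varepsilon) \le \alpha} gives
#' \deqn{n_{\min} = \frac{p(1-p)}{\alpha\,\varepsilon^2},}
#' rounded to the nearest integer (with a floor of 1). Rounding to nearest
#' reproduces the standard worked values at 15\% tolerance and 90\% confidence:
#' p = 0.6 gives 107 (from 106.7), p = 0.87 gives 50 (from 50.3), p = 0.58
#' gives 108 (from 108.3). Set `ceiling = TRUE` for a strictly conservative
#' design, which never rounds down (107, 51, 109 for the same inputs).
#'
#' @param p Success probability used for sizing.
#' @param eps Tolerance \eqn{\varepsilon} in (0, 1).
#' @param alpha Significance level \eqn{\alpha} in (0, 1); the confidence
#'   level is \eqn{1 - \alpha}.
#' @param ceiling If `TRUE`, round up instead of to nearest.
#' @return Positive integer sample size.
#' @examples
#' min_sample_size(0.6, 0.15, 0.10)   # 107
#' min_sample_size(0.87, 0.15, 0.10)  # 50
#' @export
min_sample_size <- function(p, eps, alpha, ceiling = FALSE) {
  if (any(p < 0) || any(p > 1)) stop("`p` must be a probability in [0, 1]")
  if (any(eps <= 0) || any(eps >= 1)) stop("`eps` must lie in (0, 1)")
  if (any(alpha <= 0) || any(alpha >= 1)) stop("`alpha` must lie in (0, 1)")
  n_raw <- p * (1 - p) / (alpha * eps^2)
  n <- if (ceiling) base::ceiling(n_raw) else round(n_raw)
  as.integer(pmax(1, n))
}

#' Worst-case minimum sample size
#'
#' [min_sample_size()] evaluated at `p = 0.5`, where `p(1-p)` is maximal, so
#' the result is sufficient whatever the true success probability. At 15\%
#' tolerance and 90\% confidence this gives 111 droplets; note that sizing at
#' an anticipated p of 0.6 instead gives 107, and a 10 x 10 array of 100
#' droplets is close to both.
#'
#' @inheritParams min_sample_size
#' @return Positive integer sample size.
#' @examples
#' worst_case_min_sample_size(0.15, 0.10)  # 111
#' @export
worst_case_min_sample_size <- function(eps, alpha, ceiling = FALSE) {
  min_sample_size(0.5, eps, alpha, ceiling = ceiling)
}

#' Sampling-design record
#'
#' Bundles the sizing inputs with the resulting minimum sample size and the
#' Chebyshev bound actually achieved at that size.
#'
#' @inheritParams min_sample_size
#' @return An object of class `"sampling_design"` with fields `p_worst`,
#'   `tolerance`, `alpha`, `confidence`, `n_min` and `bound_at_n_min`.
#' @examples
#' sampling_design(0.6, 0.15, 0.10)
#' @export
sampling_design <- function(p, eps, alpha, ceiling = FALSE) {
  n_min <- min_sample_size(p, eps, alpha, ceiling = ceiling)
  structure(
    list(p_worst = p, tolerance = eps, alpha = alpha, confidence = 1 - alpha,
         n_min = n_min,
         bound_at_n_min = chebyshev_deviation_bound(n_min, p, eps)),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf(
    "Chebyshev/LLN sampling design\n  p = %g, tolerance = %g, confidence = %g\n  n_min = %d droplets (deviation bound %.4f at n_min)\n",
    x$p_worst, x$tolerance, x$confidence, x$n_min, x$bound_at_n_min))
  invisible(x)
}

# volume conversions; all internal arithmetic in picoliters
PL_PER_NL <- 1e3
PL_PER_ML <- 1e9

#' Fraction of the reservoir consumed by the sampled droplets
#'
#' The sampled droplet array uses only a tiny part of the ejection reservoir:
#' 100 droplets of 7.6 nl each drawn from a 0.1 ml reservoir represent 0.76\%
#' of its volume, which is what makes the array a simple random sample of the
#' suspension.
#'
#' @param n_droplets Positive integer number of droplets.
#' @param droplet_volume_nl Droplet volume in nanoliters, strictly positive.
#' @param reservoir_volume_ml Reservoir volume in milliliters, strictly
#'   positive.
#' @return Percentage of the reservoir volume.
#' @examples
#' sampling_fraction(100, 7.6, 0.1)  # 0.76
#' @export
sampling_fraction <- function(n_droplets, droplet_volume_nl,
                              reservoir_volume_ml) {
  if (length(n_droplets) != 1L || n_droplets < 1 ||
      n_droplets != round(n_droplets)) {
    stop("`n_droplets` must be a single positive integer, got ", n_droplets)
  }
  if (droplet_volume_nl <= 0) {
    stop("`droplet_volume_nl` must be strictly positive, got ",
         droplet_volume_nl)
  }
  if (reservoir_volume_ml <= 0) {
    stop("`reservoir_volume_ml` must be strictly positive, got ",
         reservoir_volume_ml)
  }
  100 * n_droplets * (droplet_volume_nl * PL_PER_NL) /
    (reservoir_volume_ml * PL_PER_ML)
}
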