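#' Binomial occupancy law
#'
#' The number of cell-containing droplets among `n_trials` droplets is the
#' count of successes in independent Bernoulli trials: "success" is the event
#' that a droplet contains at least one cell, "failure" that it is empty.
#'
#' @param n_trials Positive integer, the number of droplets (trials).
#' @param p_success Probability of a droplet containing cells, in \[0, 1\].
#' @return An object of class `"binomial_law"` with fields `n_trials`,
#'   `p_success` and `q = 1 - p_success`, and derived moments `mean = np`
#'   and `variance = npq`.
#' @examples
#' law <- binomial_law(100, 0.583)
#' law$mean
#' @export
binomial_law <- function(n_trials, p_success) {
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1 ||
      n_trials != round(n_trials)) {
    stop("`n_trials` must be a single positive integer, got ", n_trials)
  }
  if (length(p_success) != 1L || !is.finite(p_success) ||
      p_success < 0 || p_success > 1) {
    stop("`p_success` must be a probability in [0, 1], got ", p_success)
  }
  structure(
    list(n_trials = as.integer(n_trials), p_success = p_success,
         q = 1 - p_success,
         mean = n_trials * p_success,
         variance = n_trials * p_success * (1 - p_success)),
    class = "binomial_law"
  )
}

#' @export
print.binomial_law <- function(x, ...) {
  cat(sprintf("Binomial occupancy law: n = %d, p = %g (mean %g, variance %g)\n",
              x$n_trials, x$p_success, x$mean, x$variance))
  invisible(x)
}

#' Exact binomial probability mass function
#'
#' Probability of `k` cell-containing droplets among `n_trials`. Evaluated as
#' \eqn{\binom{n}{k} p^k q^{n-k}}; for `n_trials > 50` the term is assembled
#' in log space (log-binomial-coefficient plus log powers) to avoid factorial
#' overflow, while small-n results use the direct product.
#'
#' @param law A [binomial_law()].
#' @param k Integer vector of success counts, each in `0:n_trials`.
#' @return Numeric vector of probabilities.
#' @examples
#' binomial_pmf(binomial_law(10, 0.5), 5)  # 252/1024
#' @export
binomial_pmf <- function(law, k) {
  stopifnot(inherits(law, "binomial_law"))
  n <- law$n_trials
  if (any(k != round(k)) || any(k < 0) || any(k > n)) {
    bad <- k[k != round(k) | k < 0 | k > n][1L]
    stop("`k` out of range 0..", n, ": offending value ", bad)
  }
  p <- law$p_success
  q <- law$q
  if (p == 0) return(as.numeric(k == 0))
  if (p == 1) return(as.numeric(k == n))
  if (n > 50) {
    exp(lchoose(n, k) + k * log(p) + (n - k) * log(q))
  } else {
    choose(n, k) * p^k * q^(n - k)
  }
}

#' Stirling approximation to the factorial
#'
#' \eqn{n! \approx \sqrt{2\pi n}\,(n/e)^n}. The approximation error falls as
#' roughly \eqn{1/(12n)}; at `n = 20` the relative error is already below
#' 0.5\%. By convention `stirling_factorial(0)` returns 1 exactly (the
#' approximation has no value at 0; the exact 0! is substituted).
#'
#' @param n Non-negative integer vector.
#' @return Numeric vector of approximate factorials.
#' @seealso [stirling_relative_error()] for the error against the exact
#'   factorial, [binomial_pmf_stirling()] for its use inside the binomial PMF.
#' @examples
#' stirling_factorial(1)   # 0.9221, 7.8% below 1! = 1
#' stirling_factorial(20)  # within 0.5% of 20!
#' @export
stirling_factorial <- function(n) {
  if (any(n < 0) || any(n != round(n))) {
    stop("`n` must be a non-negative integer")
  }
  ifelse(n == 0, 1, sqrt(2 * pi * n) * (n / exp(1))^n)
}

#' Relative error of the Stirling approximation
#'
#' @param n Positive integer vector (exact factorials are representable up to
#'   `n = 170` in double precision).
#' @return `|stirling - exact| / exact`, a numeric vector.
#' @examples
#' stirling_relative_error(20)  # ~0.00416, below the 0.5% mark
#' @export
stirling_relative_error <- function(n) {
  if (any(n < 1) || any(n > 170)) {
    stop("`n` must be in 1..170 for an exact reference factorial")
  }
  exact <- factorial(n)
  abs(stirling_factorial(n) - exact) / exact
}

# log of the Stirling approximation; stable for large n
stirling_log_factorial <- function(n) {
  ifelse(n == 0, 0, 0.5 * log(2 * pi * n) + n * (log(n) - 1))
}

#' Binomial PMF with Stirling-approximated factorials
#'
#' Evaluates the binomial probability with all three factorials in the
#' binomial coefficient replaced by their Stirling approximations. Because the
#' approximation has no value at 0!, the boundary cases `k = 0` and
#' `k = n_trials` fall back to the exact PMF. In the central region with
#' `n_trials >= 20` the approximation agrees with the exact PMF within about
#' 1.5\% relative error.
#'
#' @inheritParams binomial_pmf
#' @return Numeric vector of approximate probabilities.
#' @examples
#' law <- binomial_law(20, 0.5)
#' binomial_pmf_stirling(law, 10) / binomial_pmf(law, 10)
#' @export
binomial_pmf_stirling <- function(law, k) {
  stopifnot(inherits(law, "binomial_law"))
  n <- law$n_trials
  if (any(k != round(k)) || any(k < 0) || any(k > n)) {
    bad <- k[k != round(k) | k < 0 | k > n][1L]
    stop("`k` out of range 0..", n, ": offending value ", bad)
  }
  p <- law$p_success
  q <- law$q
  if (p == 0) return(as.numeric(k == 0))
  if (p == 1) return(as.numeric(k == n))
  out <- numeric(length(k))
  boundary <- k == 0 | k == n
  if (any(boundary)) out[boundary] <- binomial_pmf(law, k[boundary])
  if (any(!boundary)) {
    kk <- k[!boundary]
    lcoef <- stirling_log_factorial(n) - stirling_log_factorial(kk) -
      stirling_log_factorial(n - kk)
    out[!boundary] <- exp(lcoef + kk * log(p) + (n - kk) * log(q))
  }
  out
}

#' Poisson cell-loading law
#'
#' The number of cells in a droplet is the count of a rare event (each of the
#' many cells in the reservoir independently lands in the droplet with small
#' probability), hence Poisson with rate \eqn{\lambda} equal to the mean
#' number of cells per droplet. For the Poisson limit of a binomial with
#' finite `n` the variance is \eqn{\lambda(1 - \lambda/n)}; in the pure
#' Poisson law it equals the rate.
#'
#' @param rate Non-negative mean number of cells per droplet (\eqn{\lambda}).
#' @param sigma_sq Variance; defaults to `rate`.
#' @return An object of class `"poisson_law"` with fields `rate`, `mu` and
#'   `sigma_sq`.
#' @export
poisson_law <- function(rate, sigma_sq = rate) {
  if (length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("`rate` must be a single non-negative number, got ", rate)
  }
  structure(list(rate = rate, mu = rate, sigma_sq = sigma_sq),
            class = "poisson_law")
}

#' @export
print.poisson_law <- function(x, ...) {
  cat(sprintf("Poisson loading law: lambda = %g (variance %g)\n",
              x$rate, x$sigma_sq))
  invisible(x)
}

#' Poisson probability mass function
#'
#' \eqn{P(k) = e^{-\lambda}\lambda^k / k!}, evaluated in log space so that
#' large counts do not overflow the factorial.
#'
#' @param law A [poisson_law()] or a bare non-negative rate.
#' @param k Non-negative integer vector of cell counts.
#' @return Numeric vector of probabilities.
#' @examples
#' poisson_pmf(0.77, 1)  # 0.77 * exp(-0.77)
#' @export
poisson_pmf <- function(law, k) {
  rate <- if (inherits(law, "poisson_law")) law$rate else law
  if (length(rate) != 1L || !is.finite(rate) || rate < 0) {
    stop("rate must be a single non-negative number")
  }
  if (any(k != round(k)) || any(k < 0)) {
    stop("`k` must be non-negative integers: offending value ",
         k[k != round(k) | k < 0][1L])
  }
  if (rate == 0) return(as.numeric(k == 0))
  exp(-rate + k * log(rate) - lgamma(k + 1))
}

#' Poisson parameters of a binomial in the rare-event limit
#'
#' For a binomial with `n` trials and success probability `p`, the matching
#' Poisson rate is \eqn{\lambda = np} with finite-n variance
#' \eqn{\lambda(1 - \lambda/n)}; as \eqn{n \to \infty} with \eqn{np} fixed the
#' variance tends to the rate and the binomial PMF converges to the Poisson
#' PMF.
#'
#' @param n Positive integer number of trials.
#' @param p Success probability in \[0, 1\].
#' @return A [poisson_law()] with `rate = n * p` and
#'   `sigma_sq = rate * (1 - rate / n)`.
#' @examples
#' binomial_to_poisson_params(10, 0.1)  # rate 1, variance 0.9
#' @export
binomial_to_poisson_params <- function(n, p) {
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer")
  }
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]")
  }
  rate <- n * p
  poisson_law(rate, sigma_sq = rate * (1 - rate / n))
}

#' Combined single-target-cell law
#'
#' The event "a droplet holds exactly one target cell" combines the occupancy
#' process (does the droplet contain cells at all?) with the target-cell count
#' (Poisson, rate `lambda_target`). An empty droplet cannot hold a target
#' cell; conditional on occupancy the two components are treated as
#' independent, so
#' \deqn{P(X_s = 1) = p_{occ} \cdot \lambda_t e^{-\lambda_t},}
#' and \eqn{P(X_s = 0) = 1 - P(X_s = 1)} exactly. Since
#' \eqn{\lambda e^{-\lambda} \le e^{-1}}, the single-target probability can
#' never exceed \eqn{e^{-1} \approx 36.8\%}, attained at
#' `lambda_target = 1` with certain occupancy.
#'
#' @param p_occupied Probability that a droplet contains at least one cell.
#' @param lambda_target Mean number of target cells per droplet.
#' @return An object of class `"single_target_law"` with fields `p_occupied`,
#'   `lambda_target`, `p_single` and `p_zero = 1 - p_single`.
#' @examples
#' single_target_pmf(1, 1)$p_single  # exp(-1)
#' @export
single_target_pmf <- function(p_occupied, lambda_target) {
  if (length(p_occupied) != 1L || !is.finite(p_occupied) ||
      p_occupied < 0 || p_occupied > 1) {
    stop("`p_occupied` must be a probability in [0, 1]")
  }
  if (length(lambda_target) != 1L || !is.finite(lambda_target) ||
      lambda_target < 0) {
    stop("`lambda_target` must be non-negative")
  }
  p1 <- p_occupied * poisson_pmf(lambda_target, 1L)
  structure(
    list(p_occupied = p_occupied, lambda_target = lambda_target,
         p_single = p1, p_zero = 1 - p1),
    class = "single_target_law"
  )
}

#' @export
print.single_target_law <- function(x, ...) {
  cat(sprintf(
    "Single-target-cell law: p_occupied = %g, lambda_target = %g -> P(X_s=1) = %g\n",
    x$p_occupied, x$lambda_target, x$p_single))
  invisible(x)
}

#' Normal density used for large-sample comparisons
#'
#' As the number of sampled droplets grows, the distribution of the occupancy
#' proportion approaches a normal law; this density is used only for those
#' visual/Kolmogorov-Smirnov comparisons, never as a model of the counts.
#'
#' @param mu Mean.
#' @param sigma Standard deviation, strictly positive.
#' @param x Evaluation points.
#' @return Gaussian density values at `x`.
#' @export
normal_approximation <- function(mu, sigma, x) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be strictly positive, got ", sigma)
  }
  dnorm(x, mean = mu, sd = sigma)
}
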