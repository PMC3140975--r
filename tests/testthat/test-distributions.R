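test_that("binomial PMF matches closed forms and the dbinom oracle", {
  expect_equal(binomial_pmf(binomial_law(1, 1), 1), 1.0)
  # 252/1024 by direct combinatorial count
  expect_equal(binomial_pmf(binomial_law(10, 0.5), 5), 252 / 1024)

  # log-space path (n > 50) against two independent oracles
  law <- binomial_law(100, 0.583)
  lg <- exp(lgamma(101) - lgamma(59) - lgamma(43) +
              58 * log(0.583) + 42 * log(0.417))
  expect_equal(binomial_pmf(law, 58), lg, tolerance = 1e-12)
  expect_equal(binomial_pmf(law, 58), dbinom(58, 100, 0.583),
               tolerance = 1e-12)

  # naive small-n path agrees with dbinom across full support
  for (p in c(0.1, 0.583, 0.9)) {
    law <- binomial_law(37, p)
    expect_equal(binomial_pmf(law, 0:37), dbinom(0:37, 37, p),
                 tolerance = 1e-12)
  }

  # degenerate p
  expect_equal(binomial_pmf(binomial_law(5, 0), 0:5), c(1, 0, 0, 0, 0, 0))
  expect_equal(binomial_pmf(binomial_law(5, 1), 0:5), c(0, 0, 0, 0, 0, 1))

  expect_error(binomial_pmf(binomial_law(10, 0.5), 11), "out of range")
  expect_error(binomial_pmf(binomial_law(10, 0.5), -1), "-1")
})

test_that("binomial PMFs are normalized over their support", {
  for (law in list(binomial_law(10, 0.5), binomial_law(50, 0.271),
                   binomial_law(100, 0.583), binomial_law(500, 0.873))) {
    expect_lt(abs(sum(binomial_pmf(law, 0:law$n_trials)) - 1), 1e-12)
  }
})

test_that("Stirling approximation has the classical error behavior", {
  expect_equal(stirling_factorial(0), 1)
  expect_equal(stirling_factorial(1), sqrt(2 * pi) * exp(-1))
  expect_equal(stirling_relative_error(1), 1 - sqrt(2 * pi) * exp(-1),
               tolerance = 1e-12)
  # ~7.79% at n = 1; below 0.5% by n = 20; decreasing thereafter
  expect_equal(stirling_relative_error(1), 0.0779, tolerance = 1e-3)
  expect_lt(stirling_relative_error(20), 0.005)
  expect_lt(stirling_relative_error(40), stirling_relative_error(20))
  # Robbins bracket 1/(12n+1) < rel.err < 1/(12n) for n in 1..50
  n <- 1:50
  err <- stirling_relative_error(n)
  expect_true(all(err > 1 / (12 * n + 1)))
  expect_true(all(err < 1 / (12 * n)))
  expect_error(stirling_factorial(-1), "non-negative")
})

test_that("Stirling-approximated binomial PMF tracks the exact PMF centrally", {
  law20 <- binomial_law(20, 0.5)
  expect_lt(abs(binomial_pmf_stirling(law20, 10) - binomial_pmf(law20, 10)) /
              binomial_pmf(law20, 10), 0.015)
  law100 <- binomial_law(100, 0.583)
  expect_lt(abs(binomial_pmf_stirling(law100, 58) -
                  binomial_pmf(law100, 58)) / binomial_pmf(law100, 58), 0.01)
  # smallest legal interior input is finite and positive
  v <- binomial_pmf_stirling(binomial_law(2, 0.5), 1)
  expect_true(is.finite(v) && v > 0)
  # boundary counts fall back to the exact PMF
  expect_equal(binomial_pmf_stirling(law20, c(0, 20)),
               binomial_pmf(law20, c(0, 20)))
})

test_that("Poisson PMF matches closed forms and is normalized", {
  expect_equal(poisson_pmf(0, 0), 1.0)
  expect_equal(poisson_pmf(0.77, 1), 0.77 * exp(-0.77))
  expect_equal(poisson_pmf(1.0, 1), exp(-1))
  expect_equal(poisson_pmf(poisson_law(2.5), 0:40), dpois(0:40, 2.5),
               tolerance = 1e-12)
  expect_error(poisson_pmf(1, -1), "-1")
  # normalization after truncation at cumulative mass > 1 - 1e-12
  for (rate in c(0.05, 0.77, 1, 5)) {
    kmax <- 0
    while (ppois(kmax, rate) <= 1 - 1e-12) kmax <- kmax + 1
    expect_lt(abs(sum(poisson_pmf(rate, 0:kmax)) - 1), 1e-9)
  }
})

test_that("binomial converges to its Poisson limit as n grows", {
  expect_equal(binomial_to_poisson_params(10, 0.1)$rate, 1.0)
  expect_equal(binomial_to_poisson_params(10, 0.1)$sigma_sq, 0.9)
  expect_equal(binomial_to_poisson_params(100, 0.01)$sigma_sq, 0.99)

  # total-variation distance shrinks with n (enumerated to k = 30)
  tv <- function(n, lambda) {
    k <- 0:30
    0.5 * sum(abs(binomial_pmf(binomial_law(n, lambda / n), pmin(k, n)) *
                    (k <= n) - poisson_pmf(lambda, k)))
  }
  tvs <- sapply(c(10, 100, 1000), tv, lambda = 1)
  expect_true(all(diff(tvs) < 0))

  # sup-norm distance monotone nonincreasing over the design grid
  supd <- function(n, lambda) {
    k <- 0:60
    max(abs(binomial_pmf(binomial_law(n, lambda / n), pmin(k, n)) *
              (k <= n) - poisson_pmf(lambda, k)))
  }
  for (lambda in c(0.5, 1, 2)) {
    d <- sapply(c(10, 50, 100, 500), supd, lambda = lambda)
    expect_true(all(diff(d) <= 0))
  }
})

test_that("combined single-target law follows the occupancy-times-Poisson form", {
  expect_equal(single_target_pmf(0.5, 0)$p_single, 0)
  expect_equal(single_target_pmf(1, 1)$p_single, exp(-1))
  law <- single_target_pmf(0.7, 0.3)
  expect_equal(law$p_single, 0.7 * 0.3 * exp(-0.3))
  expect_identical(law$p_single + law$p_zero, 1)

  # maximized over lambda_target at exactly 1, for any occupancy
  grid <- seq(0.01, 5, by = 0.01)
  for (p_occ in c(0.2, 0.9)) {
    vals <- vapply(grid, function(l) single_target_pmf(p_occ, l)$p_single,
                   numeric(1))
    expect_equal(grid[which.max(vals)], 1.0)
    expect_true(all(vals <= p_occ))
    expect_true(all(vals <= exp(-1)))
  }
})

test_that("normal density helper behaves like a Gaussian", {
  expect_equal(normal_approximation(0, 1, 0), 1 / sqrt(2 * pi))
  expect_equal(normal_approximation(2, 0.5, 2 + 0.3),
               normal_approximation(2, 0.5, 2 - 0.3))
  expect_error(normal_approximation(0, 0, 0), "positive")
  expect_error(normal_approximation(0, -1, 0), "positive")
})
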