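test_that("summaries count the four encapsulation statistics by hand", {
  arr <- make_droplet_array(total = c(0, 1, 2), target = c(0, 1, 0))
  s <- summarize_array(arr)
  expect_equal(s$p_d_hat, 2 / 3)
  expect_equal(s$lambda_hat, 1.0)
  expect_identical(s$occupancy_count, 2L)
  expect_identical(s$single_target_count, 1L)
  expect_equal(s$pmf_cells, c(`0` = 1 / 3, `1` = 1 / 3, `2` = 1 / 3))
  expect_equal(sum(s$pmf_cells), 1, tolerance = 1e-12)
  expect_equal(sum(s$pmf_targets), 1, tolerance = 1e-12)

  # strict convention: a singlet must also be the only cell in its droplet
  arr2 <- make_droplet_array(total = c(1, 3), target = c(1, 1))
  expect_identical(summarize_array(arr2)$single_target_count, 2L)
  expect_identical(summarize_array(arr2, strict_singlet = TRUE)$single_target_count,
                   1L)
})

test_that("an all-empty array gives degenerate summaries", {
  s <- summarize_array(make_droplet_array(rep(0, 10)))
  expect_equal(s$p_d_hat, 0)
  expect_equal(s$lambda_hat, 0)
  expect_equal(s$pmf_cells, c(`0` = 1))
  expect_identical(s$single_target_count, 0L)
})

test_that("summarize-of-simulate is consistent at scale", {
  arr <- simulate_droplet_array(design_from_lambda(1.0, fraction = 0.1,
                                                   n_droplets = 1e5,
                                                   seed = 314))
  s <- summarize_array(arr)
  expect_lt(abs(s$lambda_hat - 1.0), 0.01)
  expect_lt(abs(s$p_d_hat - (1 - exp(-1))),
            3 * sqrt((1 - exp(-1)) * exp(-1) / 1e5))
  # independent-summation oracle for the MLE
  expect_equal(s$lambda_hat, sum(arr$total_cells) / nrow(arr))
})

test_that("lambda estimate and intervals behave across methods", {
  zero <- summarize_array(make_droplet_array(rep(0, 20)))
  ci0 <- estimate_lambda(zero)
  expect_equal(c(ci0$estimate, ci0$lower, ci0$upper), c(0, 0, 0))
  # score and exact intervals remain informative on all-zero data
  expect_gt(estimate_lambda(zero, method = "score")$upper, 0)
  expect_gt(estimate_lambda(zero, method = "exact")$upper, 0)

  # width shrinks like 1/sqrt(n)
  w <- sapply(c(100, 400), function(n) {
    s <- summarize_array(make_droplet_array(rep(c(0, 1), n / 2)))
    ci <- estimate_lambda(s)
    ci$upper - ci$lower
  })
  expect_equal(w[1] / w[2], 2, tolerance = 1e-6)

  # estimator is unbiased: mean over 1000 replicated arrays at the low
  # target-rate operating point (lambda = 0.05, n = 100)
  sums <- replicate_experiment(design_from_lambda(0.05, n_droplets = 100,
                                                  seed = 2718), 1000)
  lam_hat <- vapply(sums, `[[`, numeric(1), "lambda_hat")
  se <- sqrt(0.05 / 100 / 1000)
  expect_lt(abs(mean(lam_hat) - 0.05), 3 * se)
})

test_that("PMF distance metric is a symmetric max-abs difference in points", {
  p <- c(`0` = 0.5, `1` = 0.3, `2` = 0.2)
  expect_equal(model_fit_error(p, p), 0)
  q <- c(`0` = 0.4, `1` = 0.35, `3` = 0.25)
  expect_equal(model_fit_error(p, q), model_fit_error(q, p))
  # support union: k = 2 contributes |0.2 - 0|, k = 3 |0 - 0.25|
  expect_equal(model_fit_error(p, q), 25)
  expect_error(model_fit_error(unname(p), q), "named")
})

test_that("combined-law check reports the model-vs-data gap faithfully", {
  # no targets: both sides zero
  d0 <- design_from_lambda(0.5, fraction = 0, n_droplets = 1000, seed = 8)
  chk0 <- single_target_model_check(summarize_array(simulate_droplet_array(d0)),
                                    d0)
  expect_equal(chk0$empirical_pct, 0)
  expect_equal(chk0$model_pct, 0)

  # near-saturated occupancy: the occupancy-times-Poisson factorization is
  # nearly exact, so model and data agree within 1 percentage point at n=1e5
  d_hi <- design_from_lambda(5, fraction = 0.1, n_droplets = 1e5, seed = 123)
  chk_hi <- single_target_model_check(
    summarize_array(simulate_droplet_array(d_hi)), d_hi)
  expect_lt(chk_hi$abs_error_pp, 1)

  # moderate occupancy: the combined law multiplies the marginal thinned
  # Poisson singlet rate by p_occ, so it undershoots by a predictable gap
  d_mid <- design_from_lambda(0.77, fraction = 0.5, n_droplets = 1e5,
                              seed = 124)
  chk_mid <- single_target_model_check(
    summarize_array(simulate_droplet_array(d_mid)), d_mid)
  lam_t <- 0.77 * 0.5
  marginal <- lam_t * exp(-lam_t)
  model <- (1 - exp(-0.77)) * marginal
  expect_equal(chk_mid$model_pct, 100 * model, tolerance = 1e-10)
  expect_equal(chk_mid$abs_error_pp, 100 * (marginal - model), tolerance = 1)
  # model probability can never exceed exp(-1)
  expect_lte(chk_mid$law$p_single, exp(-1))
})

test_that("recovery study is deterministic and covers near nominal", {
  r1 <- recovery_study(c(0.1, 0.5), c(0.1, 0.5), n_droplets = 50,
                       n_replicates = 100, seed = 99)
  r2 <- recovery_study(c(0.1, 0.5), c(0.1, 0.5), n_droplets = 50,
                       n_replicates = 100, seed = 99)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 4L)
  expect_true(all(r1$coverage >= 0.85 & r1$coverage <= 1))
  # target-rate estimates track lambda * F
  expect_equal(r1$mean_lambda_target_hat,
               r1$lambda_true * r1$fraction_true, tolerance = 0.05)
  expect_error(recovery_study(numeric(0), 0.1), "non-empty")
  expect_error(recovery_study(c(0.5, 20), 0.1), "\\[0, 10\\]")
})

test_that("the occupancy proportion approaches normality as droplets increase", {
  for (p in c(0.583, 0.873)) {
    tab <- lln_demonstration(p, c(10, 25, 50, 100))
    expect_true(all(diff(tab$ks_distance) < 0))
  }
  # deterministic: exact enumeration, no sampling involved
  expect_identical(lln_demonstration(0.583), lln_demonstration(0.583))
  # independent oracle: sup over a fine grid of evaluation points at n = 10
  # (grid error is bounded by the peak normal density times the step, ~3e-5)
  p <- 0.583
  x <- seq(-0.5, 1.5, by = 1e-5)
  Fb <- pbinom(floor(x * 10 + 1e-9), 10, p)
  Fn <- pnorm(x, p, sqrt(p * (1 - p) / 10))
  expect_lt(abs(lln_demonstration(p, 10)$ks_distance - max(abs(Fb - Fn))),
            1e-4)
  # large n: the distance is already far below the n = 10 value
  expect_lt(lln_demonstration(0.5, c(10, 2000))$ks_distance[2],
            lln_demonstration(0.5, c(10, 2000))$ks_distance[1] / 5)
  expect_error(lln_demonstration(0.5, c(100, 10)), "increasing")
})
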