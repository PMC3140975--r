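#' Summarize a droplet array
#'
#' Counts the realizations of the four random variables of the encapsulation
#' process: droplets containing cells (occupancy), cells per droplet, target
#' cells per droplet, and droplets with a single target cell.
#'
#' Two single-target counting conventions exist. The default counts droplets
#' whose `target_cells` equals 1, allowing co-encapsulated non-targets (the
#' convention implied by building the combined law from occupancy and the
#' target-cell count). The strict convention additionally requires
#' `total_cells == 1`. Both counts are always computed; `strict_singlet`
#' selects which one populates `single_target_count`.
#'
#' @param array A `"droplet_array"` from [simulate_droplet_array()] or
#'   [read_droplet_table()].
#' @param strict_singlet If `TRUE`, a single-target droplet must contain
#'   exactly one cell in total.
#' @return An object of class `"count_summary"`: `n_droplets`,
#'   `occupancy_count`, `p_d_hat`, `lambda_hat` (mean total cells),
#'   `lambda_target_hat`, `pmf_cells` and `pmf_targets` (named empirical
#'   PMFs over `0:max`), `single_target_count`, `singlet_count_any`,
#'   `singlet_count_strict`, `p_single_hat`.
#' @examples
#' arr <- simulate_droplet_array(
#'   simulation_design(suspension_spec(1e5, 0.5), droplet_spec(), seed = 7))
#' summarize_array(arr)
#' @export
summarize_array <- function(array, strict_singlet = FALSE) {
  if (!inherits(array, "droplet_array")) {
    stop("`array` must be a droplet_array")
  }
  n <- nrow(array)
  if (n < 1L) stop("array has no droplets")
  total <- array$total_cells
  targets <- array$target_cells
  emp_pmf <- function(x) {
    counts <- tabulate(x + 1L, nbins = max(x) + 1L)
    setNames(counts / length(x), 0:max(x))
  }
  singlet_any <- sum(targets == 1L)
  singlet_strict <- sum(targets == 1L & total == 1L)
  single_count <- if (strict_singlet) singlet_strict else singlet_any
  structure(
    list(n_droplets = n,
         occupancy_count = sum(total > 0L),
         p_d_hat = mean(total > 0L),
         lambda_hat = mean(total),
         lambda_target_hat = mean(targets),
         pmf_cells = emp_pmf(total),
         pmf_targets = emp_pmf(targets),
         single_target_count = single_count,
         singlet_count_any = singlet_any,
         singlet_count_strict = singlet_strict,
         p_single_hat = single_count / n,
         strict_singlet = strict_singlet),
    class = "count_summary"
  )
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf(
    "Droplet count summary (n = %d)\n  occupancy: %d droplets (p_d_hat = %.3f)\n  lambda_hat = %.4g cells/droplet (targets %.4g)\n  single-target droplets: %d (%.2f%%)%s\n",
    x$n_droplets, x$occupancy_count, x$p_d_hat, x$lambda_hat,
    x$lambda_target_hat, x$single_target_count, 100 * x$p_single_hat,
    if (x$strict_singlet) " [strict: exactly one cell in total]" else ""))
  invisible(x)
}

#' Estimate the Poisson loading rate with a confidence interval
#'
#' The maximum-likelihood estimate of \eqn{\lambda} is the sample mean of the
#' per-droplet cell counts. Three interval methods are available:
#' \describe{
#'   \item{`"normal"`}{Wald interval
#'     \eqn{\hat\lambda \pm z\sqrt{\hat\lambda/n}}, truncated at 0. Simple and
#'     adequate when the expected total count \eqn{n\hat\lambda} is large, but
#'     it undercovers badly for small rates (an all-zero sample yields the
#'     degenerate interval \[0, 0\]).}
#'   \item{`"score"`}{Inverts the score test:
#'     \eqn{\lambda = \hat\lambda + z^2/2n \pm z\sqrt{\hat\lambda/n + z^2/4n^2}}.
#'     Maintains close-to-nominal coverage across the whole rate range,
#'     including rates where only a handful of cells are observed.}
#'   \item{`"exact"`}{Garwood chi-square interval on the total count;
#'     guaranteed conservative.}
#' }
#'
#' @param summary A [summarize_array()] result.
#' @param conf_level Confidence level, default 0.95.
#' @param method Interval method; default `"normal"`.
#' @return A list with `estimate`, `lower`, `upper`, `conf_level`, `method`.
#' @examples
#' arr <- simulate_droplet_array(
#'   simulation_design(suspension_spec(1e5), droplet_spec(), seed = 3))
#' estimate_lambda(summarize_array(arr), method = "score")
#' @export
estimate_lambda <- function(summary, conf_level = 0.95,
                            method = c("normal", "score", "exact")) {
  if (!inherits(summary, "count_summary")) {
    stop("`summary` must be a count_summary")
  }
  method <- match.arg(method)
  n <- summary$n_droplets
  lam <- summary$lambda_hat
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- switch(
    method,
    normal = {
      half <- z * sqrt(lam / n)
      c(max(0, lam - half), lam + half)
    },
    score = {
      center <- lam + z^2 / (2 * n)
      half <- z * sqrt(lam / n + z^2 / (4 * n^2))
      c(max(0, center - half), center + half)
    },
    exact = {
      S <- round(lam * n)
      lower <- if (S == 0) 0 else qchisq((1 - conf_level) / 2, 2 * S) / 2 / n
      upper <- qchisq(1 - (1 - conf_level) / 2, 2 * S + 2) / 2 / n
      c(lower, upper)
    }
  )
  list(estimate = lam, lower = ci[1], upper = ci[2],
       conf_level = conf_level, method = method)
}

#' Maximum absolute difference between two PMFs, in percentage points
#'
#' PMFs are given as named numeric vectors over integer supports; the
#' supports are unioned and missing entries treated as zero. The metric is
#' symmetric in its arguments.
#'
#' @param empirical_pmf,model_pmf Named numeric vectors (names are integer
#'   support points).
#' @return `100 * max_k |empirical(k) - model(k)|`.
#' @examples
#' model_fit_error(c(`0` = 0.5, `1` = 0.5), c(`0` = 0.4, `1` = 0.6))  # 10
#' @export
model_fit_error <- function(empirical_pmf, model_pmf) {
  if (is.null(names(empirical_pmf)) || is.null(names(model_pmf))) {
    stop("PMFs must be named by their integer support")
  }
  support <- sort(unique(as.integer(c(names(empirical_pmf),
                                      names(model_pmf)))))
  key <- as.character(support)
  e <- ifelse(key %in% names(empirical_pmf), empirical_pmf[key], 0)
  m <- ifelse(key %in% names(model_pmf), model_pmf[key], 0)
  100 * max(abs(e - m))
}

#' Check the combined single-target law against a simulated array
#'
#' Compares the empirical single-target rate in a summary against the
#' combined-law prediction
#' \eqn{P(X_s = 1) = p_{occ}\,\lambda_t e^{-\lambda_t}} evaluated at the
#' design's true rates (the occupancy override is honored when set). Note the
#' combined law multiplies the marginal single-target-Poisson probability by
#' the occupancy probability; under pure Poisson loading with binomial
#' thinning the marginal rate of exactly one target is
#' \eqn{\lambda F e^{-\lambda F}} with no occupancy factor, so the combined
#' law systematically undershoots at moderate loading rates and becomes exact
#' only as occupancy approaches 1. The returned record reports both numbers
#' and their gap; it does not judge it.
#'
#' @param summary A [summarize_array()] result.
#' @param design The [simulation_design()] that generated the array.
#' @return A list with `empirical_pct`, `model_pct`, `abs_error_pp`, and the
#'   `single_target_law` used.
#' @export
single_target_model_check <- function(summary, design) {
  if (!inherits(summary, "count_summary")) {
    stop("`summary` must be a count_summary")
  }
  if (!inherits(design, "simulation_design")) {
    stop("`design` must be a simulation_design")
  }
  p_occ <- design$occupancy_override %||%
    occupancy_probability(design$lambda)
  law <- single_target_pmf(p_occ, design$lambda_target)
  empirical <- summary$single_target_count / summary$n_droplets
  list(empirical_pct = 100 * empirical,
       model_pct = 100 * law$p_single,
       abs_error_pp = 100 * abs(empirical - law$p_single),
       law = law)
}

#' Parameter-recovery study over a grid of loading rates and target fractions
#'
#' Full factorial Monte Carlo: for every (\eqn{\lambda}, F) design point,
#' simulates `n_replicates` droplet arrays of `n_droplets`, estimates
#' \eqn{\lambda} (total cells) and \eqn{\lambda F} (target cells) from each,
#' and reports bias and confidence-interval coverage. The score interval is
#' the default because its coverage stays near nominal across the whole
#' tabulated rate range, down to rates where the expected total count in an
#' array is a handful of cells (see [estimate_lambda()]).
#'
#' @param lambda_grid Loading rates, each in \[0, 10\].
#' @param fraction_grid Target fractions, each in \[0, 1\].
#' @param n_droplets Droplets per simulated array (default 100, a 10 x 10
#'   grid).
#' @param n_replicates Replicates per design point.
#' @param seed Integer base seed; design points receive deterministic
#'   substream seeds.
#' @param conf_level Interval confidence level, default 0.95.
#' @param method Interval method passed to [estimate_lambda()]; default
#'   `"score"`.
#' @return A `data.frame` of class `"recovery_report"` with one row per
#'   design point: `lambda_true`, `fraction_true`, `mean_lambda_hat`,
#'   `sd_lambda_hat`, `mean_lambda_target_hat`, `sd_lambda_target_hat`,
#'   `coverage`, `bias`, `bias_se` (standard error of the mean estimate) and
#'   `z_bias = bias / bias_se`.
#' @examples
#' recovery_study(c(0.1, 0.5), 0.1, n_droplets = 50, n_replicates = 50,
#'                seed = 1)
#' @export
recovery_study <- function(lambda_grid, fraction_grid, n_droplets = 100,
                           n_replicates = 200, seed = 1L,
                           conf_level = 0.95,
                           method = c("score", "normal", "exact")) {
  if (length(lambda_grid) < 1L || any(lambda_grid < 0) ||
      any(lambda_grid > 10)) {
    stop("`lambda_grid` must be non-empty with rates in [0, 10]")
  }
  if (length(fraction_grid) < 1L || any(fraction_grid < 0) ||
      any(fraction_grid > 1)) {
    stop("`fraction_grid` must be non-empty with fractions in [0, 1]")
  }
  method <- match.arg(method)
  grid <- expand.grid(lambda_true = lambda_grid, fraction_true = fraction_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- substream_seeds(seed, nrow(grid))
  droplet <- droplet_spec(grid_rows = 1L, grid_cols = n_droplets)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lam <- grid$lambda_true[i]
    f <- grid$fraction_true[i]
    conc <- lam * PL_PER_ML / (droplet$droplet_volume_nl * PL_PER_NL)
    design <- simulation_design(
      suspension_spec(conc, target_fraction = f),
      droplet, n_droplets = n_droplets, seed = cell_seeds[i])
    sums <- replicate_experiment(design, n_replicates)
    lam_hat <- vapply(sums, `[[`, numeric(1), "lambda_hat")
    lam_t_hat <- vapply(sums, `[[`, numeric(1), "lambda_target_hat")
    covered <- vapply(sums, function(s) {
      ci <- estimate_lambda(s, conf_level = conf_level, method = method)
      ci$lower <= lam && lam <= ci$upper
    }, logical(1))
    bias_se <- sqrt(lam / n_droplets / n_replicates)
    data.frame(
      lambda_true = lam, fraction_true = f,
      mean_lambda_hat = mean(lam_hat), sd_lambda_hat = sd(lam_hat),
      mean_lambda_target_hat = mean(lam_t_hat),
      sd_lambda_target_hat = sd(lam_t_hat),
      coverage = mean(covered),
      bias = mean(lam_hat) - lam,
      bias_se = bias_se,
      z_bias = if (bias_se > 0) (mean(lam_hat) - lam) / bias_se else 0
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_droplets") <- n_droplets
  attr(out, "n_replicates") <- n_replicates
  attr(out, "conf_level") <- conf_level
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "Recovery study: %d design points, n = %d droplets, %d replicates, %s interval\n",
    nrow(x), attr(x, "n_droplets"), attr(x, "n_replicates"),
    attr(x, "method")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

# exact Kolmogorov-Smirnov distance between the Binomial(n, p)/n CDF and the
# normal CDF with mean p and sd sqrt(p(1-p)/n); sup attained at jump points
ks_binomial_normal <- function(n, p) {
  k <- 0:n
  Fb <- pbinom(k, n, p)
  Fn <- pnorm(k / n, mean = p, sd = sqrt(p * (1 - p) / n))
  max(pmax(abs(Fn - Fb), abs(Fn - c(0, Fb[-(n + 1)]))))
}

#' Law-of-large-numbers demonstration for the occupancy proportion
#'
#' For each sample size, computes the exact Kolmogorov-Smirnov distance
#' between the distribution of the binomial occupancy proportion `k/n` and
#' its normal approximation (mean `p`, sd `sqrt(p(1-p)/n)`). The distance is
#' obtained by exact enumeration of the binomial CDF -- no sampling -- so the
#' output is deterministic, and it shrinks as the number of sampled droplets
#' grows, which is what justifies treating a 10 x 10 droplet array as
#' approximately normal.
#'
#' @param p Occupancy probability in (0, 1).
#' @param n_values Increasing vector of sample sizes.
#' @return A `data.frame` with columns `n` and `ks_distance`.
#' @examples
#' lln_demonstration(0.583, c(10, 25, 50, 100))
#' @export
lln_demonstration <- function(p, n_values = c(10, 25, 50, 100)) {
  if (length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must lie strictly between 0 and 1")
  }
  if (any(n_values < 1) || any(n_values != round(n_values)) ||
      is.unsorted(n_values, strictly = TRUE)) {
    stop("`n_values` must be strictly increasing positive integers")
  }
  data.frame(
    n = as.integer(n_values),
    ks_distance = vapply(n_values, ks_binomial_normal, numeric(1), p = p)
  )
}
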