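#' Cell suspension specification
#'
#' Composition of the ejection reservoir: cell loading concentration, the
#' fraction of cells that are the desired target type, and the volume of a
#' single cell. The default cell volume, 0.5236 pl, is that of a 10 micrometer
#' diameter sphere; it is a configurable default inferred from typical
#' mammalian cell size, not a measured constant.
#'
#' @param concentration_per_ml Cell loading concentration in cells/ml,
#'   non-negative.
#' @param target_fraction Fraction of cells that are targets, in \[0, 1\].
#' @param cell_volume_pl Single-cell volume in picoliters, strictly positive.
#' @return An object of class `"suspension_spec"`.
#' @examples
#' suspension_spec(1e5, target_fraction = 0.1)
#' @export
suspension_spec <- function(concentration_per_ml,
                            target_fraction = 0,
                            cell_volume_pl = 0.5236) {
  if (length(concentration_per_ml) != 1L || !is.finite(concentration_per_ml) ||
      concentration_per_ml < 0) {
    stop("`concentration_per_ml` must be a single non-negative number")
  }
  if (length(target_fraction) != 1L || !is.finite(target_fraction) ||
      target_fraction < 0 || target_fraction > 1) {
    stop("`target_fraction` must lie in [0, 1], got ", target_fraction)
  }
  if (length(cell_volume_pl) != 1L || !is.finite(cell_volume_pl) ||
      cell_volume_pl <= 0) {
    stop("`cell_volume_pl` must be strictly positive, got ", cell_volume_pl)
  }
  structure(
    list(concentration_per_ml = concentration_per_ml,
         target_fraction = target_fraction,
         cell_volume_pl = cell_volume_pl),
    class = "suspension_spec"
  )
}

#' @export
print.suspension_spec <- function(x, ...) {
  cat(sprintf(
    "Cell suspension: %.3g cells/ml, %.1f%% targets, cell volume %.4g pl\n",
    x$concentration_per_ml, 100 * x$target_fraction, x$cell_volume_pl))
  invisible(x)
}

#' Droplet / ejection geometry specification
#'
#' Defaults reflect a drop-on-demand ejector placing a 10 x 10 array of
#' 7.7 nl droplets from a 0.1 ml reservoir.
#'
#' @param droplet_volume_nl Droplet volume in nanoliters, strictly positive.
#' @param reservoir_volume_ml Ejection reservoir volume in milliliters.
#' @param grid_rows,grid_cols Positive integers; their product is the intended
#'   number of sampled droplets.
#' @return An object of class `"droplet_spec"`.
#' @examples
#' droplet_spec()  # 7.7 nl droplets, 10 x 10 array
#' @export
droplet_spec <- function(droplet_volume_nl = 7.7,
                         reservoir_volume_ml = 0.1,
                         grid_rows = 10, grid_cols = 10) {
  if (length(droplet_volume_nl) != 1L || !is.finite(droplet_volume_nl) ||
      droplet_volume_nl <= 0) {
    stop("`droplet_volume_nl` must be strictly positive")
  }
  if (length(reservoir_volume_ml) != 1L || !is.finite(reservoir_volume_ml) ||
      reservoir_volume_ml <= 0) {
    stop("`reservoir_volume_ml` must be strictly positive")
  }
  for (g in c(grid_rows, grid_cols)) {
    if (length(g) != 1L || g < 1 || g != round(g)) {
      stop("grid dimensions must be positive integers")
    }
  }
  structure(
    list(droplet_volume_nl = droplet_volume_nl,
         reservoir_volume_ml = reservoir_volume_ml,
         grid_rows = as.integer(grid_rows),
         grid_cols = as.integer(grid_cols)),
    class = "droplet_spec"
  )
}

#' @export
print.droplet_spec <- function(x, ...) {
  cat(sprintf(
    "Droplet spec: %.3g nl droplets, %d x %d array, reservoir %.3g ml\n",
    x$droplet_volume_nl, x$grid_rows, x$grid_cols, x$reservoir_volume_ml))
  invisible(x)
}

#' Expected cells per droplet (the Poisson loading rate)
#'
#' \eqn{\lambda = C \cdot V}: loading concentration times droplet volume,
#' with units handled internally (cells/ml times nl). The target-cell rate is
#' the thinned \eqn{\lambda F}.
#'
#' @param suspension A [suspension_spec()].
#' @param droplet A [droplet_spec()].
#' @return A list with `lambda` (mean total cells per droplet) and
#'   `lambda_target` (mean target cells per droplet).
#' @examples
#' expected_cells_per_droplet(suspension_spec(1e5, 0.1), droplet_spec(7.7))
#' @export
expected_cells_per_droplet <- function(suspension, droplet) {
  stopifnot(inherits(suspension, "suspension_spec"),
            inherits(droplet, "droplet_spec"))
  lambda <- suspension$concentration_per_ml *
    (droplet$droplet_volume_nl * PL_PER_NL) / PL_PER_ML
  list(lambda = lambda, lambda_target = lambda * suspension$target_fraction)
}

#' Droplet occupancy probability under Poisson loading
#'
#' Probability that a droplet contains at least one cell: the complement of
#' the Poisson empty-droplet event, \eqn{1 - e^{-\lambda}}.
#'
#' @param lambda Non-negative Poisson loading rate(s).
#' @return Probability in \[0, 1).
#' @examples
#' occupancy_probability(0.77)  # 0.537
#' @export
occupancy_probability <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("`lambda` must be non-negative")
  }
  -expm1(-lambda)
}

#' Minimum droplet volume for a target cell-to-droplet volume fraction
#'
#' A droplet must be at least \eqn{V_{cell} / f} to keep the cell volume at or
#' below a fraction `f` of the droplet. With the default 0.5236 pl cell and
#' f = 1.7\% this gives the 30.8 pl minimum droplet volume at which
#' encapsulation approaches certainty.
#'
#' @param cell_volume_pl Single-cell volume in picoliters, strictly positive.
#' @param volume_fraction Cell-to-droplet volume ratio in (0, 1).
#' @return Minimum droplet volume in picoliters.
#' @examples
#' min_droplet_volume(0.5236, 0.017)  # 30.8 pl
#' @export
min_droplet_volume <- function(cell_volume_pl, volume_fraction) {
  if (any(cell_volume_pl <= 0)) stop("`cell_volume_pl` must be positive")
  if (any(volume_fraction <= 0) || any(volume_fraction >= 1)) {
    stop("`volume_fraction` must lie strictly between 0 and 1, got ",
         volume_fraction[volume_fraction <= 0 | volume_fraction >= 1][1L])
  }
  cell_volume_pl / volume_fraction
}

#' Maximum cell loading concentration for a droplet volume
#'
#' The concentration at which a droplet of the given volume holds exactly one
#' cell in expectation: \eqn{C_{max} = 1 / V}. A 30.8 pl droplet gives
#' 32.5e6 cells/ml; a 7.7 nl droplet gives 1.30e5 cells/ml.
#'
#' @param droplet_volume_pl Droplet volume in picoliters, strictly positive.
#' @return Concentration in cells/ml.
#' @examples
#' max_cell_concentration(30.8)  # 3.25e7 cells/ml
#' @export
max_cell_concentration <- function(droplet_volume_pl) {
  if (any(droplet_volume_pl <= 0)) {
    stop("`droplet_volume_pl` must be positive")
  }
  PL_PER_ML / droplet_volume_pl
}

#' Cell-to-droplet volume fraction
#'
#' Two conventions are supported. The default, `"expected-total"`, is the
#' expected total cell volume per droplet over the droplet volume,
#' \eqn{100\,\lambda V_{cell} / V_{drop}} (linear in concentration).
#' `"per-cell"` is the volume of one cell over the droplet volume,
#' \eqn{100\,V_{cell}/V_{drop}}, the convention under which a 0.5236 pl cell
#' in a 30.8 pl droplet gives 1.7\%. Published volume-fraction figures do not
#' always state which convention they use; both are provided.
#'
#' @inheritParams expected_cells_per_droplet
#' @param mode `"expected-total"` (default) or `"per-cell"`.
#' @return Volume fraction as a percentage.
#' @export
volume_fraction <- function(suspension, droplet,
                            mode = c("expected-total", "per-cell")) {
  stopifnot(inherits(suspension, "suspension_spec"),
            inherits(droplet, "droplet_spec"))
  mode <- match.arg(mode)
  droplet_pl <- droplet$droplet_volume_nl * PL_PER_NL
  if (mode == "per-cell") {
    100 * suspension$cell_volume_pl / droplet_pl
  } else {
    lambda <- expected_cells_per_droplet(suspension, droplet)$lambda
    100 * lambda * suspension$cell_volume_pl / droplet_pl
  }
}

#' Saturating-exponential fit of encapsulation probability vs concentration
#'
#' Encapsulation probability rises with loading concentration and saturates;
#' the curve \eqn{P(C) = a(1 - e^{-bC})} is fitted by least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}) with deterministic starting
#' values \eqn{a_0 = 1.5\max(P)}, \eqn{b_0 = 0.5} and convergence tolerance
#' 1e-10 on the parameter change, capped at 500 iterations.
#'
#' @param concentrations Concentrations in units of 1e5 cells/ml; at least 3
#'   strictly positive, distinct values.
#' @param probabilities Encapsulation probabilities in percent, same length.
#' @return An object of class `"saturation_fit"`: `a` (amplitude, percent),
#'   `b` (rate per 1e5 cells/ml), `r_squared`, `adj_r_squared`, `residuals`,
#'   `fitted`, `converged`, and the data.
#' @examples
#' fit <- fit_saturation_curve(c(0.5, 1, 1.5, 2), c(27.1, 58.3, 76.8, 87.3))
#' fit$r_squared
#' @export
fit_saturation_curve <- function(concentrations, probabilities) {
  if (length(concentrations) < 3L) {
    stop("at least 3 points are required, got ", length(concentrations))
  }
  if (length(probabilities) != length(concentrations)) {
    stop("`concentrations` and `probabilities` must have equal length")
  }
  if (any(!is.finite(concentrations)) || any(!is.finite(probabilities))) {
    stop("inputs must be finite")
  }
  if (any(concentrations <= 0) || anyDuplicated(concentrations)) {
    stop("`concentrations` must be strictly positive and distinct")
  }
  dat <- data.frame(C = concentrations, P = probabilities)
  start <- list(a = max(probabilities) * 1.5, b = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      P ~ a * (1 - exp(-b * C)), data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(
      list(a = NA_real_, b = NA_real_, r_squared = NA_real_,
           adj_r_squared = NA_real_, residuals = rep(NA_real_, nrow(dat)),
           fitted = rep(NA_real_, nrow(dat)), converged = FALSE,
           message = conditionMessage(fit), data = dat),
      class = "saturation_fit"))
  }
  co <- coef(fit)
  res <- as.numeric(resid(fit))
  ss_res <- sum(res^2)
  ss_tot <- sum((dat$P - mean(dat$P))^2)
  n <- nrow(dat)
  r2 <- 1 - ss_res / ss_tot
  structure(
    list(a = co[["a"]], b = co[["b"]], r_squared = r2,
         adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2 - 1),
         residuals = res, fitted = as.numeric(fitted(fit)),
         converged = fit$convInfo$isConv %||% TRUE,
         message = "converged", data = dat),
    class = "saturation_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.saturation_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Saturation fit did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Saturation fit P(C) = a(1 - exp(-bC)): a = %.4g%%, b = %.4g per 1e5 cells/ml\n  R^2 = %.4f (adjusted %.4f), %d points\n",
    x$a, x$b, x$r_squared, x$adj_r_squared, nrow(x$data)))
  invisible(x)
}

#' Evaluate a saturation fit at new concentrations
#'
#' @param object A `"saturation_fit"`.
#' @param newdata Optional numeric vector of concentrations (1e5 cells/ml);
#'   defaults to the fitted ones.
#' @param ... Unused.
#' @return Predicted probabilities in percent.
#' @export
predict.saturation_fit <- function(object, newdata = NULL, ...) {
  C <- if (is.null(newdata)) object$data$C else newdata
  object$a * (1 - exp(-object$b * C))
}
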