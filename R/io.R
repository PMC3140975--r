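DROPLET_TABLE_HEADER <- c("droplet_id", "row", "col", "total_cells",
                          "target_cells")

#' Write a droplet array to CSV (with optional design sidecar)
#'
#' The table has the fixed header
#' `droplet_id,row,col,total_cells,target_cells` and is written with a fixed
#' format (no quoting, `\n` line endings), so identical arrays produce
#' byte-identical files. When the array carries a simulation design and
#' `metadata = TRUE`, a JSON sidecar `<path>.json` records the full design
#' and seed.
#'
#' @param array A `"droplet_array"`.
#' @param path Output CSV path.
#' @param metadata Write the design sidecar when available? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_droplet_table <- function(array, path, metadata = TRUE) {
  if (!inherits(array, "droplet_array")) {
    stop("`array` must be a droplet_array")
  }
  df <- as.data.frame(array)[, DROPLET_TABLE_HEADER]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(DROPLET_TABLE_HEADER, collapse = ","), con, sep = "\n")
  writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con,
             sep = "\n")
  design <- attr(array, "design")
  if (metadata && !is.null(design)) {
    jsonlite::write_json(design_to_list(design), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
  }
  invisible(path)
}

design_to_list <- function(design) {
  list(
    suspension = unclass(design$suspension),
    droplet = unclass(design$droplet),
    n_droplets = design$n_droplets,
    seed = design$seed,
    occupancy_override = design$occupancy_override,
    lambda = design$lambda,
    lambda_target = design$lambda_target
  )
}

#' Read and validate a droplet table
#'
#' Expects the exact header `droplet_id,row,col,total_cells,target_cells`.
#' Every row is validated: counts must be non-negative integers,
#' `target_cells` cannot exceed `total_cells`, and droplet ids must be
#' unique; violations are reported with their line number in the file.
#' A header-only file yields a valid zero-droplet array (downstream
#' summaries reject it).
#'
#' @param path CSV path.
#' @return A `"droplet_array"` data frame.
#' @export
read_droplet_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, DROPLET_TABLE_HEADER)) {
    stop("bad header: expected '",
         paste(DROPLET_TABLE_HEADER, collapse = ","), "' but found '",
         paste(header, collapse = ","), "'")
  }
  df <- read.csv(path, colClasses = "integer")
  # line numbers in the file are row index + 1 (header line)
  bad_counts <- which(df$total_cells < 0 | df$target_cells < 0)
  if (length(bad_counts) > 0) {
    stop("negative cell count at line ", bad_counts[1L] + 1L)
  }
  bad_target <- which(df$target_cells > df$total_cells)
  if (length(bad_target) > 0) {
    stop("target_cells exceeds total_cells at line ", bad_target[1L] + 1L)
  }
  dup <- which(duplicated(df$droplet_id))
  if (length(dup) > 0) {
    stop("duplicate droplet_id at line ", dup[1L] + 1L)
  }
  class(df) <- c("droplet_array", "data.frame")
  df
}

default_pipeline_config <- function() {
  list(
    concentration_per_ml = 1e5,
    target_fraction = 0.1,
    cell_volume_pl = 0.5236,
    droplet_volume_nl = 7.7,
    reservoir_volume_ml = 0.1,
    grid_rows = 10L,
    grid_cols = 10L,
    n_droplets = 100L,
    occupancy_override = NULL,
    sample_size_p = 0.6,
    tolerance = 0.15,
    confidence = 0.90,
    seed = 42L
  )
}

#' Run the full simulate-summarize-estimate-design pipeline
#'
#' One reproducible invocation: simulate a droplet array, summarize the four
#' count statistics, estimate the loading rate, check the combined
#' single-target law, and report the sampling design and physical design
#' quantities. The report embeds the package version, the fully resolved
#' configuration and the seed, and is serialized with stable key order and
#' 12-significant-digit floats, so identical configurations produce
#' byte-identical reports.
#'
#' @param config Named list overriding any of the default configuration
#'   entries (`concentration_per_ml`, `target_fraction`, `cell_volume_pl`,
#'   `droplet_volume_nl`, `reservoir_volume_ml`, `grid_rows`, `grid_cols`,
#'   `n_droplets`, `occupancy_override`, `sample_size_p`, `tolerance`,
#'   `confidence`, `seed`).
#' @param out_prefix Optional path prefix; when given, writes
#'   `<prefix>_droplets.csv` (plus design sidecar) and `<prefix>_report.json`.
#' @return The report, an object of class `"pipeline_report"` (a named list).
#' @examples
#' rep <- run_pipeline(list(seed = 42))
#' rep$sampling_design$n_min
#' @export
run_pipeline <- function(config = list(), out_prefix = NULL) {
  unknown <- setdiff(names(config), names(default_pipeline_config()))
  if (length(unknown) > 0) {
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(default_pipeline_config(), config)

  suspension <- suspension_spec(cfg$concentration_per_ml,
                                cfg$target_fraction, cfg$cell_volume_pl)
  droplet <- droplet_spec(cfg$droplet_volume_nl, cfg$reservoir_volume_ml,
                          cfg$grid_rows, cfg$grid_cols)
  design <- simulation_design(suspension, droplet,
                              n_droplets = cfg$n_droplets, seed = cfg$seed,
                              occupancy_override = cfg$occupancy_override)
  array <- simulate_droplet_array(design)
  summary <- summarize_array(array)
  lam <- estimate_lambda(summary)
  check <- single_target_model_check(summary, design)
  sdesign <- sampling_design(cfg$sample_size_p, cfg$tolerance,
                             1 - cfg$confidence)

  report <- list(
    tool = "dropenc",
    version = as.character(packageVersion("dropenc")),
    config = cfg,
    design = design_to_list(design),
    summary = list(
      n_droplets = summary$n_droplets,
      occupancy_count = summary$occupancy_count,
      p_d_hat = summary$p_d_hat,
      lambda_hat = summary$lambda_hat,
      lambda_target_hat = summary$lambda_target_hat,
      single_target_count = summary$single_target_count,
      p_single_hat = summary$p_single_hat,
      pmf_cells = as.list(summary$pmf_cells),
      pmf_targets = as.list(summary$pmf_targets)
    ),
    lambda_estimate = lam,
    single_target_check = list(
      empirical_pct = check$empirical_pct,
      model_pct = check$model_pct,
      abs_error_pp = check$abs_error_pp
    ),
    sampling_design = unclass(sdesign),
    physical_design = list(
      lambda = design$lambda,
      lambda_target = design$lambda_target,
      occupancy = occupancy_probability(design$lambda),
      volume_fraction_pct = volume_fraction(suspension, droplet),
      volume_fraction_per_cell_pct = volume_fraction(suspension, droplet,
                                                     mode = "per-cell"),
      sampling_fraction_pct = sampling_fraction(cfg$n_droplets,
                                                cfg$droplet_volume_nl,
                                                cfg$reservoir_volume_ml)
    )
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_prefix)) {
    write_droplet_table(array, paste0(out_prefix, "_droplets.csv"))
    jsonlite::write_json(unclass(report), paste0(out_prefix, "_report.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE,
                         null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("dropenc pipeline report (v%s, seed %d)\n", x$version,
              x$config$seed))
  cat(sprintf("  lambda = %.4g, occupancy model %.3f, observed p_d_hat %.3f\n",
              x$design$lambda, x$physical_design$occupancy,
              x$summary$p_d_hat))
  cat(sprintf("  lambda_hat = %.4g [%.4g, %.4g] (%s)\n",
              x$lambda_estimate$estimate, x$lambda_estimate$lower,
              x$lambda_estimate$upper, x$lambda_estimate$method))
  cat(sprintf("  single-target: empirical %.2f%% vs combined law %.2f%%\n",
              x$single_target_check$empirical_pct,
              x$single_target_check$model_pct))
  cat(sprintf("  sampling design: n_min = %d at p = %g, tol %g, conf %g\n",
              x$sampling_design$n_min, x$sampling_design$p_worst,
              x$sampling_design$tolerance, x$sampling_design$confidence))
  invisible(x)
}
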