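# build a droplet_array directly from count vectors (10 columns, row-major)
make_droplet_array <- function(total, target = rep(0L, length(total))) {
  n <- length(total)
  idx <- seq_len(n) - 1L
  df <- data.frame(
    droplet_id = seq_len(n),
    row = idx %/% 10L,
    col = idx %% 10L,
    total_cells = as.integer(total),
    target_cells = as.integer(target)
  )
  class(df) <- c("droplet_array", "data.frame")
  df
}

# design with loading rate lambda set directly (unit-consistent concentration)
design_from_lambda <- function(lambda, fraction = 0, n_droplets = 100,
                               seed = 1L, occupancy_override = NULL) {
  droplet <- droplet_spec(grid_rows = 1L, grid_cols = n_droplets)
  conc <- lambda * 1e6 / droplet$droplet_volume_nl  # lambda = C * V_nl * 1e-6
  simulation_design(suspension_spec(conc, target_fraction = fraction),
                    droplet, n_droplets = n_droplets, seed = seed,
                    occupancy_override = occupancy_override)
}

# brute-force least-squares grid search for P(C) = a(1 - exp(-bC));
# independent oracle for fit_saturation_curve
grid_search_saturation <- function(C, P,
                                   a_grid = seq(50, 300, by = 0.5),
                                   b_grid = seq(0.05, 2, by = 0.002)) {
  G <- outer(b_grid, C, function(b, cc) 1 - exp(-b * cc))  # |b| x |C|
  sb1 <- as.numeric(G %*% P)     # sum_i P_i g_i(b)
  sb2 <- rowSums(G^2)            # sum_i g_i(b)^2
  sumP2 <- sum(P^2)
  # SS(a, b) = sum P^2 - 2 a sb1(b) + a^2 sb2(b)
  SS <- sumP2 - 2 * outer(a_grid, sb1) + outer(a_grid^2, sb2)
  idx <- arrayInd(which.min(SS), dim(SS))
  list(a = a_grid[idx[1]], b = b_grid[idx[2]], ss = min(SS),
       a_step = a_grid[2] - a_grid[1], b_step = b_grid[2] - b_grid[1])
}
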