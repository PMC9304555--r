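# Shared fixtures: small, fast synthetic objects built in code.

# A quick noise-free curve at modest sampling for structural tests.
quick_curve <- function(K = 40, noise = 0, seed = NULL, n = 100, ...) {
  simulate_force_curve(K, noise_sd_um = noise, seed = seed, n_samples = n, ...)
}

# Hand-built force curve (bypasses the simulator) for edge-case tests.
raw_curve <- function(z, d, probe = probe_spec()) {
  structure(list(curve_id = "raw", grid_x_um = 0, grid_y_um = 0,
                 piezo_z_um = z, deflection_um = d, probe = probe,
                 truth = NULL),
            class = "force_curve")
}

# A small stiffness map straight from a matrix (no force simulation).
map_from_matrix <- function(K, step_um = 15) {
  structure(list(K_grid = K, step_um = step_um, origin_um = c(x = 0, y = 0),
                 ap_axis = "cols"),
            class = "stiffness_map")
}

# Region summary with prescribed per-segment anterior/posterior values.
summary_from_pairs <- function(anterior, posterior) {
  out <- data.frame(segment_id = seq_along(anterior),
                    stage = 7L + seq_along(anterior),
                    n_anterior = 8L, n_posterior = 7L,
                    mean_K_anterior = anterior, mean_K_posterior = posterior,
                    median_K_anterior = anterior,
                    median_K_posterior = posterior)
  attr(out, "center") <- "mean"
  class(out) <- c("region_summary", "data.frame")
  out
}

# Cell-density table with one stage and given per-embryo halves.
density_table <- function(anterior, posterior, stage = 12L) {
  n <- length(anterior)
  out <- data.frame(embryo_id = rep(sprintf("e%02d", seq_len(n)), 2),
                    stage = stage,
                    half = rep(c("anterior", "posterior"), each = n),
                    roi_area_um2 = 2500,
                    n_nuclei = c(anterior, posterior),
                    rel_density = c(anterior, posterior))
  attr(out, "scheme") <- "prescribed"
  class(out) <- c("cell_density_table", "data.frame")
  out
}
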