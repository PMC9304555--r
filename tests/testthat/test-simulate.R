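# Forward simulation: force balance, trigger, determinism, grids, counts.

test_that("simulated deflection solves the cantilever-sample balance", {
  fc <- quick_curve(K = 40, n = 120)
  k_c <- fc$probe$spring_constant
  post <- fc$piezo_z_um > fc$truth$contact_z_um
  d <- fc$deflection_um[post]
  delta <- (fc$piezo_z_um[post] - fc$truth$contact_z_um) - d
  resid <- abs(1000 * k_c * d - hertz_force(delta, 40, fc$probe$bead_radius_um))
  expect_lt(max(resid), 1e-6)
})

test_that("the trigger truncates at the set force", {
  fc <- quick_curve(K = 40, n = 160)
  f <- 1000 * fc$probe$spring_constant * fc$deflection_um
  n <- length(f)
  expect_gt(f[n], 3)                   # first exceedance kept
  expect_true(all(f[-n] <= 3))
  expect_lt(f[n] - 3, f[n] - f[n - 1]) # within one sample's force increment
})

test_that("final indentation matches the closed-form Hertz inversion", {
  fc <- quick_curve(K = 40, n = 160)
  n <- length(fc$piezo_z_um)
  delta_end <- (fc$piezo_z_um[n] - fc$truth$contact_z_um) - fc$deflection_um[n]
  # delta(3 nN) = (F / ((4/3) K sqrt(R)))^(2/3) = 5.550828 um at K = 40 Pa
  spacing <- diff(fc$piezo_z_um[1:2])
  expect_lt(abs(delta_end - 5.550828), spacing)
})

test_that("simulation is reproducible by seed and validates inputs", {
  a <- quick_curve(noise = 0.005, seed = 7)
  b <- quick_curve(noise = 0.005, seed = 7)
  c <- quick_curve(noise = 0.005, seed = 8)
  expect_identical(a$deflection_um, b$deflection_um)
  expect_false(identical(a$deflection_um, c$deflection_um))
  expect_error(quick_curve(noise = 0.005), "seed")
  expect_error(simulate_force_curve(40, n_samples = 8), ">= 16")
  expect_error(simulate_force_curve(40, z_range_um = c(0, 2), contact_z_um = 5,
                                    noise_sd_um = 0),
               "span the contact")
})

test_that("grid simulation yields one curve per point with coordinate-keyed noise", {
  tf <- make_truth_field(40, 4, n_segments = 3, n_rows_DV = 3)
  bundle <- simulate_grid(tf, noise_sd_um = 0.005, seed = 5, n_samples = 60)
  expect_length(bundle, 135)
  # per-point substream: the curve at (r, c) equals a standalone simulation
  # with the derived seed, independent of traversal order
  r <- 2L; c <- 17L
  fc <- simulate_force_curve(tf$K_true[r, c], noise_sd_um = 0.005,
                             seed = somistiff:::derive_seed(5, r, c),
                             n_samples = 60)
  idx <- which(vapply(bundle, function(x) x$curve_id, "") == "r02_c17")
  expect_equal(bundle[[idx]]$deflection_um, fc$deflection_um)
  expect_equal(bundle[[idx]]$grid_x_um, 16 * 15)
})

test_that("noise-free curves are identical down each D/V column", {
  tf <- make_truth_field(40, 4, n_segments = 1, n_rows_DV = 3)
  bundle <- simulate_grid(tf, noise_sd_um = 0, n_samples = 60)
  ids <- vapply(bundle, function(x) x$curve_id, "")
  expect_identical(bundle[[which(ids == "r01_c05")]]$deflection_um,
                   bundle[[which(ids == "r03_c05")]]$deflection_um)
})

test_that("cell-count tables have the declared structure and contrast", {
  cc <- simulate_cell_counts(n_embryos = 4, stages = 8:12, seed = 2)
  expect_identical(nrow(cc), 4L * 5L * 2L)
  counts <- table(cc$embryo_id, cc$stage, cc$half)
  expect_true(all(counts == 1))
  expect_identical(length(unique(cc$roi_area_um2)), 1L)
  expect_true(all(cc$n_nuclei >= 0))
  # reproducibility
  expect_identical(cc, simulate_cell_counts(n_embryos = 4, stages = 8:12, seed = 2))
  # prescribed contrast, vanishing dispersion: posterior ~ 1.5 x anterior
  big <- simulate_cell_counts(n_embryos = 400, stages = 12,
                              contrast_by_stage = c("12" = 1.5),
                              dispersion = 0, seed = 3)
  ratio <- mean(big$n_nuclei[big$half == "posterior"]) /
    mean(big$n_nuclei[big$half == "anterior"])
  expect_equal(ratio, 1.5, tolerance = 0.03)
  expect_error(simulate_cell_counts(stages = integer(0), seed = 1), "empty stage")
  expect_error(simulate_cell_counts(stages = 8:12), "seed")
})
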