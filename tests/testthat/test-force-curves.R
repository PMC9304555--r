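# Curve processing: baseline, contact detection, indentation, Hertz fit.

test_that("correct_baseline removes offset and tilt and is idempotent", {
  fc <- quick_curve(n = 120)
  fc$deflection_um <- fc$deflection_um + 0.01           # offset
  cb <- correct_baseline(fc)
  w <- seq_len(36)
  expect_lt(abs(mean(cb$deflection_um[w])), 1e-9)

  fc2 <- quick_curve(n = 120, baseline_tilt = 1e-4)
  cb2 <- correct_baseline(fc2)
  slope <- coef(lm(cb2$deflection_um[w] ~ cb2$piezo_z_um[w]))[2]
  expect_lt(abs(slope), 1e-6)

  cb3 <- correct_baseline(cb2)
  expect_lt(max(abs(cb3$deflection_um - cb2$deflection_um)), 1e-9)

  expect_error(correct_baseline(fc, precontact_fraction = 0.9), "\\(0, 0.8\\]")
  expect_error(correct_baseline(quick_curve(n = 20), precontact_fraction = 0.2),
               ">= 8")
})

test_that("contact detection is exact on noise-free curves across moduli", {
  for (K in c(10, 36, 44, 100)) {
    fc <- quick_curve(K = K, n = 120)
    cp <- find_contact_point(fc)
    spacing <- diff(fc$piezo_z_um[1:2])
    expect_lte(abs(cp$contact_z_um - fc$truth$contact_z_um), spacing)
  }
})

test_that("contact detection is translation-equivariant and offset/tilt-invariant", {
  fc <- quick_curve(K = 40, n = 120)
  cp <- find_contact_point(fc)
  shifted <- fc
  shifted$piezo_z_um <- fc$piezo_z_um + 3.7
  expect_equal(find_contact_point(shifted)$contact_z_um,
               cp$contact_z_um + 3.7)
  tilted <- fc
  tilted$deflection_um <- fc$deflection_um + 0.02 + 8e-4 * fc$piezo_z_um
  expect_equal(find_contact_point(tilted)$contact_index, cp$contact_index)
})

test_that("curves that never leave the noise floor raise a detection error", {
  z <- seq(0, 10, length.out = 120)
  expect_error(find_contact_point(raw_curve(z, rep(0, 120))), "noise floor")
  set.seed(1)
  expect_error(find_contact_point(raw_curve(z, rnorm(120, 0, 0.005))),
               "noise floor")
})

test_that("noisy contact detection is unbiased at its statistical accuracy", {
  # 200 seeded curves at 5 nm deflection noise, K = 40 Pa, default probe.
  # The baseline-profiled scan reaches the information bound (~0.21 um sd
  # with baseline nuisance); assert unbiasedness and that accuracy.
  err_um <- vapply(1:200, function(s) {
    fc <- simulate_force_curve(40, noise_sd_um = 0.005, seed = s,
                               n_samples = 160)
    find_contact_point(fc)$contact_z_um - fc$truth$contact_z_um
  }, numeric(1))
  expect_lt(abs(mean(err_um)), 0.05)
  expect_lte(unname(quantile(abs(err_um), 0.95)), 0.5)
})

test_that("indentation starts at zero and rises monotonically without noise", {
  fc <- quick_curve(K = 40, n = 120)
  cp <- find_contact_point(fc)
  ind <- compute_indentation(fc, cp)
  expect_equal(ind$delta_um[1], 0)
  expect_equal(ind$force_nN[1], 0)
  expect_true(all(diff(ind$delta_um) > 0))
  # trigger realizes the 3 nN set force
  expect_equal(max(ind$force_nN), 3, tolerance = 0.02)
})

test_that("fit_hertz recovers K and is linear in force", {
  for (K in c(10, 36, 44, 100)) {
    fc <- quick_curve(K = K, n = 120)
    ft <- process_curve(fc)
    expect_true(ft$converged)
    expect_equal(ft$K_Pa, K, tolerance = 5e-3)
  }
  # doubling force at fixed indentation doubles K exactly
  fc <- quick_curve(K = 40, n = 120)
  ind <- compute_indentation(fc, find_contact_point(fc))
  f1 <- fit_hertz(ind, max_force_nN = 10)
  ind2 <- ind
  ind2$force_nN <- 2 * ind$force_nN
  f2 <- fit_hertz(ind2, max_force_nN = 10)
  expect_equal(f2$K_Pa, 2 * f1$K_Pa, tolerance = 1e-12)
})

test_that("fit_hertz flags pathological inputs instead of lying", {
  fc <- quick_curve(K = 40, n = 120)
  ind <- compute_indentation(fc, find_contact_point(fc))
  neg <- ind
  neg$force_nN <- -neg$force_nN
  ftn <- fit_hertz(neg, max_force_nN = 10)
  expect_false(ftn$converged)
  expect_lt(ftn$K_Pa, 0)
  zero <- ind
  zero$delta_um <- rep(0, nrow(zero))
  expect_error(fit_hertz(zero, max_force_nN = 10), "all-zero indentation")
  # the soft-tissue regime violates delta << R and is flagged
  soft <- quick_curve(K = 10, n = 120)
  ft_soft <- process_curve(soft)
  expect_false(ft_soft$hertz_small_indentation)   # delta_max ~ 0.75 R
  stiff <- quick_curve(K = 100, n = 120)
  expect_true(process_curve(stiff)$hertz_small_indentation)
})

test_that("median K stays within 5% over 200 noisy curves", {
  Ks <- vapply(1:200, function(s) {
    fc <- simulate_force_curve(40, noise_sd_um = 0.005, seed = s,
                               n_samples = 160)
    process_curve(fc)$K_Pa
  }, numeric(1))
  expect_lt(abs(median(Ks) / 40 - 1), 0.05)
})

test_that("process_curve returns a flagged missing fit on failure", {
  z <- seq(0, 10, length.out = 120)
  ft <- process_curve(raw_curve(z, rep(0, 120)))
  expect_false(ft$converged)
  expect_true(is.na(ft$K_Pa))
  expect_match(ft$error, "noise floor")
})
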