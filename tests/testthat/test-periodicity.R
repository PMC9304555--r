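# Sinusoid initialization, fitting, canonicalization, and summaries.

test_that("initialization follows the extrema/segment-length scheme", {
  t <- 0:44
  prof <- data.frame(t = t, K_Pa = 40 + 4 * sin(2 * pi / 15 * t))
  init <- sinusoid_init(prof, 15, "unknown")
  expect_equal(init$C0, (max(prof$K_Pa) + min(prof$K_Pa)) / 2)
  expect_equal(init$alpha0, max(prof$K_Pa) - init$C0)
  expect_equal(init$omega0, 2 * pi / 15)
  expect_equal(init$phi0_candidates, c(0, pi))
  expect_equal(sinusoid_init(prof, 15, "posterior")$phi0_candidates, 0)
  expect_equal(sinusoid_init(prof, 15, "anterior")$phi0_candidates, pi)

  expect_error(sinusoid_init(data.frame(t = 0:44, K_Pa = rep(40, 45)), 15),
               "degenerate")
  expect_error(sinusoid_init(prof[1:20, ], 15), "two segments")
})

test_that("a noise-free sinusoid is recovered to high precision with R = 1", {
  t <- 0:44
  prof <- data.frame(t = t, K_Pa = 40 + 4 * sin(0.42 * t + pi))
  fit <- fit_sinusoid(prof)
  expect_true(fit$converged)
  expect_equal(fit$C, 40, tolerance = 1e-6)
  expect_equal(fit$alpha, 4, tolerance = 1e-6)
  expect_equal(fit$omega, 0.42, tolerance = 1e-6)
  expect_equal(fit$phi, pi, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$pearson_R, 1, tolerance = 1e-8)
})

test_that("parameters are canonical: alpha >= 0, phi in [0, 2*pi)", {
  t <- 0:44
  # y = 40 - 4 sin(0.42 t) is the same curve as 40 + 4 sin(0.42 t + pi)
  prof <- data.frame(t = t, K_Pa = 40 - 4 * sin(0.42 * t))
  fit <- fit_sinusoid(prof)
  expect_gte(fit$alpha, 0)
  expect_gte(fit$phi, 0)
  expect_lt(fit$phi, 2 * pi)
  expect_equal(fit$alpha, 4, tolerance = 1e-6)
  expect_equal(fit$phi, pi, tolerance = 1e-5)
})

test_that("a constant shift moves C and nothing else", {
  t <- 0:44
  prof <- data.frame(t = t, K_Pa = 40 + 4 * sin(0.42 * t + 1))
  f1 <- fit_sinusoid(prof)
  prof2 <- prof
  prof2$K_Pa <- prof$K_Pa + 7.5
  f2 <- fit_sinusoid(prof2)
  expect_equal(f2$C - f1$C, 7.5, tolerance = 1e-8)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-8)
  expect_equal(f2$omega, f1$omega, tolerance = 1e-8)
  expect_equal(f2$phi, f1$phi, tolerance = 1e-7)
})

test_that("missing points are dropped and the minimum size is enforced", {
  t <- 0:44
  y <- 40 + 4 * sin(0.42 * t + pi)
  y[c(5, 17, 30)] <- NA
  fit <- fit_sinusoid(data.frame(t = t, K_Pa = y))
  expect_identical(fit$n_points, 42L)
  expect_equal(fit$omega, 0.42, tolerance = 1e-6)
  expect_error(fit_sinusoid(data.frame(t = 0:6, K_Pa = y[1:7]),
                            init = sinusoid_init(data.frame(t = t, K_Pa = y))),
               ">= 8")
})

test_that("frequency recovery degrades monotonically with profile noise", {
  t <- 0:44
  truth <- 40 + 2 * pi * sin(2 * pi / 15 * t)
  med_err <- vapply(c(0, 1, 2, 4), function(sd_k) {
    errs <- vapply(1:100, function(s) {
      y <- truth + withr::with_seed(s, rnorm(45, 0, sd_k))
      ft <- fit_sinusoid(data.frame(t = t, K_Pa = y))
      abs(ft$omega - 2 * pi / 15)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) >= 0))
  # and the noisy estimates stay centred on the generating frequency
  om <- vapply(1:100, function(s) {
    y <- truth + withr::with_seed(s, rnorm(45, 0, 2))
    fit_sinusoid(data.frame(t = t, K_Pa = y))$omega
  }, numeric(1))
  expect_lt(abs(mean(om) - 2 * pi / 15), 3 * sd(om))
})

test_that("periodicity_summary follows the stated conventions", {
  t <- 0:44
  fit <- fit_sinusoid(data.frame(t = t, K_Pa = 40 + 4 * sin(0.42 * t)))
  s1 <- periodicity_summary(list(fit))
  expect_equal(s1$omega_mean, fit$omega)
  expect_identical(s1$omega_sd, 0)
  expect_identical(s1$n, 1L)

  s5 <- periodicity_summary(rep(list(fit), 5))
  expect_identical(s5$omega_sd, 0)
  expect_identical(s5$n, 5L)

  bad <- structure(list(converged = FALSE), class = "sinusoid_fit")
  s <- periodicity_summary(list(fit, bad))
  expect_identical(s$n_excluded, 1L)
  expect_error(periodicity_summary(list(bad)), "no converged")
})
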