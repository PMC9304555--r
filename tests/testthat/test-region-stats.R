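# Half-segment annotation, summaries, normality gate, paired tests,
# and cell-density comparisons.

test_that("assign_halves splits segments with the tie-to-anterior rule", {
  ann <- assign_halves(45, 15, starts_with = "anterior")
  expect_identical(nrow(ann), 3L)
  expect_true(all(ann$anterior_end - ann$anterior_start + 1L == 8L))
  expect_true(all(ann$posterior_end - ann$posterior_start + 1L == 7L))
  labels <- half_labels(ann)
  expect_identical(labels[1:8], rep("anterior", 8))
  expect_identical(labels[9:15], rep("posterior", 7))

  # partial terminal segment dropped
  expect_identical(nrow(assign_halves(44, 15)), 2L)
  expect_error(assign_halves(45, 15, offset = 45), "offset")
  expect_error(assign_halves(10, 15), "no full segment")

  # synthetic truth labels equal the annotation labels at matching offset
  tf <- make_truth_field(40, 4, phase = 0)
  ann2 <- assign_halves(45, 15, starts_with = tf$starts_with)
  expect_identical(half_labels(ann2), tf$half_labels)
})

test_that("summarize_regions computes per-half centers and excludes empty halves", {
  K <- matrix(36, nrow = 1, ncol = 15)
  ann <- assign_halves(15, 15, starts_with = "anterior")
  s <- summarize_regions(K, ann)
  expect_equal(s$mean_K_anterior, 36)
  expect_equal(s$median_K_anterior, 36)

  # square-wave truth: anterior 36, posterior 44 exactly
  tf <- make_truth_field(40, 4, profile = "square", n_rows_DV = 3)
  ann2 <- assign_halves(45, 15, starts_with = tf$starts_with)
  s2 <- summarize_regions(tf$K_true, ann2)
  expect_equal(s2$mean_K_anterior, rep(36, 3))
  expect_equal(s2$mean_K_posterior, rep(44, 3))
  expect_equal(s2$median_K_posterior, rep(44, 3))

  # a segment with an all-missing half is excluded with a warning
  K3 <- tf$K_true
  K3[, ann2$posterior_start[2]:ann2$posterior_end[2]] <- NA
  expect_warning(s3 <- summarize_regions(K3, ann2), "excluded")
  expect_identical(nrow(s3), 2L)
})

test_that("the Shapiro-Wilk gate selects the constructed branch", {
  set.seed(42)
  a <- rnorm(21, 40, 3)
  b <- rnorm(21, 44, 3)
  expect_identical(normality_gate(a, b)$test, "paired-t")
  # normal data passes the gate in the large majority of seeds
  picks <- vapply(1:50, function(s) {
    withr::with_seed(s, normality_gate(rnorm(21), rnorm(21))$test)
  }, character(1))
  expect_gte(mean(picks == "paired-t"), 0.8)

  # exponentiated normals: skewed raw, normal after log10
  set.seed(42)
  la <- 10^rnorm(30, 1, 0.6)
  lb <- 10^rnorm(30, 1.2, 0.6)
  expect_identical(normality_gate(la, lb)$test, "paired-t-log10")

  # a zero blocks the log branch -> wilcoxon
  expect_identical(normality_gate(c(la[1:29], 0), lb)$test, "wilcoxon")
  expect_error(normality_gate(1:2, 1:5), ">= 3")
})

test_that("paired t-test matches the closed-form t CDF", {
  s <- summary_from_pairs(c(30, 31, 32), c(30, 31, 32) + c(7, 8, 9))
  gate <- structure(list(test = "paired-t", alpha_normal = 0.01),
                    class = "test_selection")
  cmp <- compare_regions(s, gate = gate)
  d <- c(7, 8, 9)
  t_manual <- mean(d) / (sd(d) / sqrt(3))       # 8 / (1/sqrt(3)) = 13.856
  p_manual <- 2 * pt(-abs(t_manual), df = 2)    # ~0.00517
  expect_equal(cmp$statistic, t_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_manual, tolerance = 1e-9)
  expect_equal(cmp$direction_Pa, 8)

  # mean-zero differences with spread: p near 1
  s0 <- summary_from_pairs(c(30, 31, 32), c(31, 30.5, 31.5))
  cmp0 <- compare_regions(s0, gate = gate)
  expect_gt(cmp0$p_value, 0.9)

  # zero-variance differences: degenerate, flagged, not an error
  sd0 <- summary_from_pairs(c(30, 31, 32), c(35, 36, 37))
  expect_warning(cmpd <- compare_regions(sd0, gate = gate), "degenerate")
  expect_true(cmpd$degenerate)
  expect_true(is.na(cmpd$p_value))
  expect_error(compare_regions(summary_from_pairs(1:2, 3:4)), ">= 3")
})

test_that("exact Wilcoxon p matches full rank enumeration", {
  tab <- density_table(c(1, 2, 3), c(4, 5, 6))
  cmp <- compare_density(tab)
  # enumerate all C(6,3) = 20 assignments of ranks to the first group
  sums <- combn(6, 3, sum)
  p_enum <- 2 * mean(sums <= sum(1:3))
  expect_equal(p_enum, 0.1)
  expect_equal(cmp$p_value, p_enum, tolerance = 1e-12)

  # identical groups: p = 1
  same <- density_table(c(1, 2, 3), c(1, 2, 3))
  expect_equal(compare_density(same)$p_value, 1, tolerance = 1e-6)

  # all-tied values: flagged p = 1
  tied <- density_table(c(2, 2, 2), c(2, 2, 2))
  cmpt <- compare_density(tied)
  expect_true(cmpt$all_tied)
  expect_identical(cmpt$p_value, 1)
  expect_error(compare_density(density_table(1:2, 3:4)), "fewer than")
})

test_that("cell-density normalization schemes match hand arithmetic", {
  tab <- data.frame(embryo_id = "e1", stage = 12L,
                    half = c("anterior", "posterior"), roi_area_um2 = 2500,
                    n_nuclei = c(100, 130))
  m <- relative_cell_density(tab, "mean-of-all-ROIs")
  expect_equal(m$rel_density, c(100, 130) / 115, tolerance = 1e-12)
  r <- relative_cell_density(tab, "relative-to-anterior")
  expect_equal(r$rel_density, c(1, 1.3))

  # scale invariance of both schemes
  tab2 <- tab
  tab2$n_nuclei <- tab$n_nuclei * 2
  expect_equal(relative_cell_density(tab2, "mean-of-all-ROIs")$rel_density,
               m$rel_density)
  expect_equal(relative_cell_density(tab2, "relative-to-anterior")$rel_density,
               r$rel_density)

  tab3 <- rbind(tab, data.frame(embryo_id = "e1", stage = 13L,
                                half = c("anterior", "posterior"),
                                roi_area_um2 = 2500, n_nuclei = c(0, 50)))
  expect_warning(r3 <- relative_cell_density(tab3, "relative-to-anterior"),
                 "zero anterior")
  expect_identical(nrow(r3), 2L)
})

test_that("detection power is non-decreasing in the stiffness contrast", {
  rate <- vapply(c(0, 4, 8), function(contrast) {
    hits <- vapply(1:200, function(s) {
      tf <- make_truth_field(40, contrast / 2, profile = "square",
                             n_segments = 7, n_rows_DV = 3,
                             k_noise_sd = 4, seed = 10000 + s)
      ann <- assign_halves(105, 15, starts_with = tf$starts_with)
      summ <- summarize_regions(tf$K_true, ann)
      cmp <- compare_regions(summ)
      !is.na(cmp$p_value) && cmp$p_value < 0.05 && cmp$direction_Pa > 0
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lte(rate[1], 0.1)   # size under the null
  expect_gte(rate[3], 0.9)   # power at the calibrated contrast
})
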