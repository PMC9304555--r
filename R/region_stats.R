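# Anterior vs posterior half-sclerotome statistics: per-region summaries,
# Shapiro-Wilk-gated paired tests, and cell-density comparisons.

#' Per-half-segment stiffness summaries
#'
#' Computes the mean and median K per anterior and posterior half of each
#' segment, from either a full map (all selected rows pooled) or an A/P
#' profile. Both center statistics are always recorded; `center` only
#' selects which one downstream tests use by default. Segments with an
#' empty half are excluded (counted in the `n_excluded` attribute).
#'
#' @param x A `stiffness_map`, `ap_profile`, numeric matrix (cols = A/P)
#'   or numeric vector.
#' @param annotation A `segment_annotation` from [assign_halves()].
#' @param center `"mean"` or `"median"`: the default center statistic.
#' @return A data frame of class `region_summary`: one row per segment with
#'   `segment_id`, `stage`, `n_anterior`, `n_posterior`,
#'   `mean_K_anterior`, `mean_K_posterior`, `median_K_anterior`,
#'   `median_K_posterior`.
#' @export
summarize_regions <- function(x, annotation, center = c("mean", "median")) {
  center <- match.arg(center)
  vals <- if (inherits(x, "stiffness_map")) {
    x$K_grid
  } else if (inherits(x, "ap_profile")) {
    matrix(x$K_Pa, nrow = 1)
  } else if (is.matrix(x)) {
    x
  } else {
    matrix(as.numeric(x), nrow = 1)
  }
  half_vals <- function(from, to) {
    v <- as.numeric(vals[, from:to, drop = FALSE])
    v[!is.na(v)]
  }
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    a <- half_vals(annotation$anterior_start[i], annotation$anterior_end[i])
    p <- half_vals(annotation$posterior_start[i], annotation$posterior_end[i])
    if (length(a) == 0 || length(p) == 0) return(NULL)
    data.frame(segment_id = annotation$segment_id[i],
               stage = annotation$stage[i],
               n_anterior = length(a), n_posterior = length(p),
               mean_K_anterior = mean(a), mean_K_posterior = mean(p),
               median_K_anterior = stats::median(a),
               median_K_posterior = stats::median(p))
  })
  kept <- Filter(Negate(is.null), rows)
  n_excluded <- nrow(annotation) - length(kept)
  if (n_excluded > 0) {
    warning(sprintf("summarize_regions: %d segment(s) excluded (empty half)",
                    n_excluded), call. = FALSE)
  }
  if (length(kept) == 0) stop_input("summarize_regions: no segment has data in both halves")
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "center") <- center
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Shapiro-Wilk normality gate for two-sample comparisons
#'
#' Test-selection rule: a paired t-test when both samples pass the
#' Shapiro-Wilk normality test at `p >= alpha_normal` (default 0.01); a
#' paired t-test on log10-transformed values when both samples pass only
#' after log10 (requires strictly positive values); otherwise a Wilcoxon
#' rank-sum test. Deterministic for identical inputs.
#'
#' @param values_a,values_b Numeric samples (n >= 3 each).
#' @param alpha_normal Significance level of the normality gate.
#' @return An object of class `test_selection`: `test` (one of
#'   `"paired-t"`, `"paired-t-log10"`, `"wilcoxon"`), the Shapiro-Wilk
#'   p-values on raw (and, when attempted, log10) scale.
#' @export
normality_gate <- function(values_a, values_b, alpha_normal = 0.01) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop_input("normality_gate: need >= 3 values per sample")
  }
  sw <- function(v) if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  p_a <- sw(values_a)
  p_b <- sw(values_b)
  test <- NULL
  p_log <- c(NA_real_, NA_real_)
  if (p_a >= alpha_normal && p_b >= alpha_normal) {
    test <- "paired-t"
  } else if (all(values_a > 0) && all(values_b > 0)) {
    p_log <- c(sw(log10(values_a)), sw(log10(values_b)))
    if (all(p_log >= alpha_normal)) test <- "paired-t-log10"
  }
  if (is.null(test)) test <- "wilcoxon"
  structure(list(test = test, alpha_normal = alpha_normal,
                 shapiro_p = c(a = p_a, b = p_b),
                 shapiro_p_log10 = c(a = p_log[1], b = p_log[2])),
            class = "test_selection")
}

#' @export
print.test_selection <- function(x, ...) {
  cat(sprintf("Test selection: %s (Shapiro-Wilk p = %.3g / %.3g at gate %g)\n",
              x$test, x$shapiro_p[["a"]], x$shapiro_p[["b"]], x$alpha_normal))
  invisible(x)
}

#' Compare anterior and posterior half-segment stiffness
#'
#' Two-tailed comparison of paired per-segment (anterior, posterior)
#' center values, using the test chosen by the normality gate: paired t
#' (possibly on log10 values) or Wilcoxon. The Wilcoxon branch is the
#' unpaired rank-sum test by default; `paired_wilcoxon = TRUE` switches to
#' the signed-rank test. The direction is reported as the mean posterior
#' minus anterior difference. Zero-variance paired differences yield a
#' degenerate result (`p_value = NA`, flagged), not an error.
#'
#' @param summaries A `region_summary` (>= 3 segments).
#' @param gate A `test_selection`; computed from the data when `NULL`.
#' @param center `"mean"` or `"median"` per-half values to compare;
#'   defaults to the summary's recorded choice.
#' @param paired_wilcoxon Use the signed-rank test in the Wilcoxon branch.
#' @return An object of class `region_comparison`: `test_name`,
#'   `statistic`, `p_value`, `direction_Pa`, `normality`, `n_segments`,
#'   `degenerate`, and the per-segment table.
#' @export
compare_regions <- function(summaries, gate = NULL,
                            center = attr(summaries, "center"),
                            paired_wilcoxon = FALSE) {
  if (is.null(center)) center <- "mean"
  a <- summaries[[paste0(center, "_K_anterior")]]
  p <- summaries[[paste0(center, "_K_posterior")]]
  if (length(a) < 3) stop_input("compare_regions: need >= 3 paired segments")
  if (is.null(gate)) gate <- normality_gate(a, p)
  diffs <- p - a
  degenerate <- stats::sd(diffs) == 0
  if (degenerate && gate$test != "wilcoxon") {
    warning("compare_regions: zero variance of paired differences; p-value degenerate",
            call. = FALSE)
    res <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    res <- switch(gate$test,
      "paired-t" = stats::t.test(p, a, paired = TRUE),
      "paired-t-log10" = stats::t.test(log10(p), log10(a), paired = TRUE),
      "wilcoxon" = stats::wilcox.test(p, a, paired = paired_wilcoxon,
                                      exact = NULL))
  }
  test_name <- if (gate$test == "wilcoxon" && paired_wilcoxon) {
    "wilcoxon-signed-rank"
  } else {
    gate$test
  }
  structure(list(test_name = test_name,
                 statistic = unname(res$statistic),
                 p_value = res$p.value,
                 direction_Pa = mean(diffs),
                 normality = gate,
                 n_segments = length(a),
                 degenerate = degenerate,
                 center = center,
                 per_segment = summaries),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("Posterior vs anterior half-segments (n = %d, %s of %s K):\n",
              x$n_segments, x$center, "per-segment"))
  cat(sprintf("  %s: statistic = %.4g, two-tailed p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  cat(sprintf("  mean posterior - anterior difference = %.3g Pa\n",
              x$direction_Pa))
  if (x$degenerate) cat("  WARNING: degenerate (zero-variance) differences\n")
  invisible(x)
}

#' Normalize nucleus counts to relative cell densities
#'
#' Two normalization schemes:
#' \describe{
#'   \item{`"mean-of-all-ROIs"`}{each count divided by the grand mean of
#'     all that embryo's ROI counts (default).}
#'   \item{`"relative-to-anterior"`}{each posterior count divided by its
#'     paired anterior count; anterior becomes 1. Pairs with a zero
#'     anterior count are excluded with a warning.}
#' }
#' Both schemes are invariant to a common scaling of all counts.
#'
#' @param table A `cell_count_table` (see [simulate_cell_counts()]).
#' @param scheme Normalization scheme.
#' @return The table with a `rel_density` column; scheme recorded in the
#'   `scheme` attribute.
#' @export
relative_cell_density <- function(table,
                                  scheme = c("mean-of-all-ROIs",
                                             "relative-to-anterior")) {
  scheme <- match.arg(scheme)
  need <- c("embryo_id", "stage", "half", "n_nuclei")
  if (!all(need %in% names(table))) {
    stop_input("relative_cell_density: table must carry columns %s",
               paste(need, collapse = ", "))
  }
  out <- as.data.frame(table)
  if (scheme == "mean-of-all-ROIs") {
    grand <- stats::ave(out$n_nuclei, out$embryo_id, FUN = mean)
    out$rel_density <- out$n_nuclei / grand
  } else {
    key <- paste(out$embryo_id, out$stage)
    ant <- out$n_nuclei[out$half == "anterior"][
      match(key, key[out$half == "anterior"])]
    drop <- ant == 0
    if (any(drop)) {
      warning(sprintf("relative_cell_density: %d pair(s) with zero anterior count excluded",
                      length(unique(key[drop]))), call. = FALSE)
      out <- out[!drop, ]
      ant <- ant[!drop]
    }
    out$rel_density <- out$n_nuclei / ant
  }
  attr(out, "scheme") <- scheme
  class(out) <- c("cell_density_table", "data.frame")
  out
}

#' Per-stage Wilcoxon comparison of anterior vs posterior cell density
#'
#' For each somite stage, a two-sided Wilcoxon rank-sum test of the
#' normalized anterior vs posterior densities across embryos (exact
#' p-values for small tie-free samples, normal approximation with mid-rank
#' tie correction otherwise). Stages where all values tie report p = 1
#' with a tie flag.
#'
#' @param normalized A `cell_density_table` from [relative_cell_density()].
#' @param min_embryos Minimum embryos per stage (default 3).
#' @return A data frame of class `density_comparison` with `stage`,
#'   `n_embryos`, `mean_anterior`, `mean_posterior`, `W`, `p_value`,
#'   `all_tied`.
#' @export
compare_density <- function(normalized, min_embryos = 3) {
  stopifnot(all(c("stage", "half", "rel_density") %in% names(normalized)))
  stages <- sort(unique(normalized$stage))
  rows <- lapply(stages, function(s) {
    a <- normalized$rel_density[normalized$stage == s &
                                  normalized$half == "anterior"]
    p <- normalized$rel_density[normalized$stage == s &
                                  normalized$half == "posterior"]
    if (length(a) < min_embryos || length(p) < min_embryos) {
      stop_input("compare_density: stage %s has fewer than %d embryos", s,
                 min_embryos)
    }
    tied <- length(unique(c(a, p))) == 1L
    if (tied) {
      w <- NA_real_; pv <- 1
    } else {
      exact <- length(a) <= 25 && length(p) <= 25 &&
        !anyDuplicated(c(a, p))
      wt <- suppressWarnings(stats::wilcox.test(a, p, exact = exact,
                                                correct = TRUE))
      w <- unname(wt$statistic); pv <- wt$p.value
    }
    data.frame(stage = s, n_embryos = length(a),
               mean_anterior = mean(a), mean_posterior = mean(p),
               W = w, p_value = pv, all_tied = tied)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scheme") <- attr(normalized, "scheme")
  class(out) <- c("density_comparison", "data.frame")
  out
}
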