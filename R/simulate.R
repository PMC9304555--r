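# Forward simulation of AFM approach curves and cell-count tables.

#' Simulate a single AFM approach force-distance curve
#'
#' Forward model of a sphere-tipped cantilever indenting a Hertzian
#' half-space of modulus `K_true`. Before contact the deflection is zero
#' (plus noise); after contact each sample's deflection `d` solves the
#' cantilever-sample force balance
#' `k_c * d = (4/3) * K * sqrt(R) * (z - z_contact - d)^(3/2)`
#' (indentation `delta = z - d` measured from contact), found by bracketed
#' root-finding on `d` in `[0, z - z_contact]` to 1e-9 um. The approach is
#' truncated at the first sample whose force exceeds the probe's set force,
#' emulating the acquisition trigger. Additive Gaussian deflection noise and
#' an optional linear baseline tilt model measurement imperfections.
#'
#' When `z_range_um` is omitted the piezo ramp is built so the true contact
#' point falls exactly on a sample and the ramp just covers the trigger
#' force for the given `K_true`.
#'
#' @param K_true True apparent reduced modulus in Pa.
#' @param probe A [probe_spec()].
#' @param contact_z_um True contact position in um (default: chosen by the
#'   automatic ramp geometry).
#' @param z_range_um Optional `c(start, stop)` piezo range in um; must span
#'   the contact point.
#' @param n_samples Number of piezo samples (>= 16).
#' @param noise_sd_um SD of additive Gaussian deflection noise, in um
#'   (default 0.005 um = 5 nm).
#' @param baseline_tilt Linear baseline drift in um deflection per um piezo
#'   travel (default 0).
#' @param seed RNG seed; required when `noise_sd_um > 0`.
#' @param curve_id,grid_x_um,grid_y_um Identification and raster position
#'   carried into downstream tables.
#' @param precontact_fraction Fraction of samples before contact when the
#'   ramp is built automatically.
#'
#' @return An object of class `force_curve`: list with `curve_id`,
#'   `grid_x_um`, `grid_y_um`, `piezo_z_um`, `deflection_um`, `probe`, and a
#'   `truth` record (true contact, K, noise, seed) for synthetic provenance.
#' @examples
#' fc <- simulate_force_curve(40, noise_sd_um = 0)
#' range(fc$deflection_um)
#' @export
simulate_force_curve <- function(K_true, probe = probe_spec(),
                                 contact_z_um = NULL, z_range_um = NULL,
                                 n_samples = 160, noise_sd_um = 0.005,
                                 baseline_tilt = 0, seed = NULL,
                                 curve_id = "curve", grid_x_um = 0,
                                 grid_y_um = 0, precontact_fraction = 1 / 3) {
  if (K_true <= 0) stop_input("simulate_force_curve: K_true must be positive")
  if (!is_count(n_samples) || n_samples < 16) {
    stop_input("simulate_force_curve: n_samples must be an integer >= 16")
  }
  if (noise_sd_um > 0 && is.null(seed)) {
    stop_input("simulate_force_curve: seed is required when noise_sd_um > 0")
  }
  k_c <- probe$spring_constant
  R <- probe$bead_radius_um
  d_trig <- probe$set_force_nN / (1000 * k_c)
  delta_trig <- hertz_indentation(probe$set_force_nN, K_true, R)

  if (is.null(z_range_um)) {
    n_pre <- max(2L, round(n_samples * precontact_fraction))
    n_post <- n_samples - n_pre - 1L
    if (n_post < 8L) stop_input("simulate_force_curve: too few post-contact samples")
    spacing <- 1.05 * (delta_trig + d_trig) / n_post
    z <- spacing * (seq_len(n_samples) - 1)
    contact_z_um <- z[n_pre + 1L]  # exactly on-sample
  } else {
    if (is.null(contact_z_um)) {
      contact_z_um <- z_range_um[1] + diff(z_range_um) * precontact_fraction
    }
    if (contact_z_um <= z_range_um[1] || contact_z_um >= z_range_um[2]) {
      stop_input("simulate_force_curve: z_range (%g, %g) must span the contact point %g",
                 z_range_um[1], z_range_um[2], contact_z_um)
    }
    z <- seq(z_range_um[1], z_range_um[2], length.out = n_samples)
  }

  A <- hertz_prefactor(K_true, R)  # nN / um^(3/2)
  s <- z - contact_z_um
  d <- numeric(n_samples)
  post <- which(s > 0)
  for (i in post) {
    g <- function(x) 1000 * k_c * x - A * (s[i] - x)^1.5
    root <- tryCatch(
      stats::uniroot(g, lower = 0, upper = s[i], tol = 1e-12)$root,
      error = function(e) {
        stop_input("simulate_force_curve: no deflection root at z = %g um (K_true = %g Pa, range %g..%g um): %s",
                   z[i], K_true, min(z), max(z), conditionMessage(e))
      })
    d[i] <- root
  }

  force_nN <- deflection_to_force_nN(d, k_c)
  trig <- which(force_nN > probe$set_force_nN)[1]
  keep <- if (is.na(trig)) seq_len(n_samples) else seq_len(trig)
  z <- z[keep]
  d <- d[keep]

  d <- d + baseline_tilt * (z - z[1])
  if (noise_sd_um > 0) {
    d <- d + local_seed(seed, stats::rnorm(length(d), sd = noise_sd_um))
  }

  structure(list(curve_id = curve_id, grid_x_um = grid_x_um,
                 grid_y_um = grid_y_um, piezo_z_um = z, deflection_um = d,
                 probe = probe,
                 truth = list(contact_z_um = contact_z_um, K_true = K_true,
                              noise_sd_um = noise_sd_um, seed = seed)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force curve %s at (%g, %g) um: %d samples, z %g..%g um\n",
              x$curve_id, x$grid_x_um, x$grid_y_um, length(x$piezo_z_um),
              min(x$piezo_z_um), max(x$piezo_z_um)))
  invisible(x)
}

#' Simulate a raster scan of force curves over a truth field
#'
#' Generates one force curve per grid point of a [make_truth_field()] field.
#' `grid_x_um = (col - 1) * step` runs along the antero-posterior axis,
#' `grid_y_um = (row - 1) * step` along dorso-ventral. Each point uses an
#' independent RNG substream derived from `(seed, row, col)`, so the bundle
#' is reproducible and independent of traversal order.
#'
#' @param truth A `truth_field`.
#' @param probe A [probe_spec()].
#' @param noise_sd_um Deflection noise SD in um.
#' @param seed Master seed for the per-point noise substreams.
#' @param n_samples Samples per curve.
#' @param ... Passed to [simulate_force_curve()].
#'
#' @return An object of class `force_bundle`: list of `force_curve`s with
#'   the probe, step size, seed and truth attached as attributes.
#' @examples
#' tf <- make_truth_field(40, 4, n_segments = 1, n_rows_DV = 2)
#' bundle <- simulate_grid(tf, noise_sd_um = 0, n_samples = 60)
#' length(bundle)  # 30 curves
#' @export
simulate_grid <- function(truth, probe = probe_spec(), noise_sd_um = 0.005,
                          seed = 1L, n_samples = 160, ...) {
  stopifnot(inherits(truth, "truth_field"))
  nr <- nrow(truth$K_true)
  nc <- ncol(truth$K_true)
  curves <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      k <- k + 1L
      curves[[k]] <- tryCatch(
        simulate_force_curve(truth$K_true[r, c], probe = probe,
                             n_samples = n_samples,
                             noise_sd_um = noise_sd_um,
                             seed = derive_seed(seed, r, c),
                             curve_id = sprintf("r%02d_c%02d", r, c),
                             grid_x_um = (c - 1) * truth$step_um,
                             grid_y_um = (r - 1) * truth$step_um, ...),
        error = function(e) {
          stop_input("simulate_grid: failure at grid row %d, col %d: %s",
                     r, c, conditionMessage(e))
        })
    }
  }
  structure(curves, class = "force_bundle", probe = probe,
            step_um = truth$step_um, seed = seed, truth = truth)
}

#' Simulate stage-resolved anterior/posterior cell-count tables
#'
#' Emulates nucleus counts in fixed-area regions of interest (ROIs) placed
#' in the anterior and posterior half of each sclerotome across somite
#' stages. Anterior counts are drawn around `baseline_density`; posterior
#' counts around `baseline_density * ratio(stage)`, where the default ratio
#' is 1 before `onset_stage` (stage X) and rises linearly by
#' `contrast_step` per stage from there — the stage-dependent posterior
#' densification the analysis is meant to detect. Counts follow a negative
#' binomial law with overdispersion `dispersion` (Poisson when
#' `dispersion = 0`).
#'
#' @param n_embryos Number of embryos (default 5).
#' @param stages Integer somite-stage indices (default `5:15`, i.e. V-XV).
#' @param baseline_density Mean anterior nucleus count per ROI.
#' @param contrast_by_stage Optional named numeric vector of
#'   posterior/anterior ratios per stage (names = stage index); overrides
#'   the default ramp.
#' @param onset_stage Stage at which the posterior contrast begins
#'   (default 10, stage X).
#' @param contrast_step Ratio increment per stage past onset (default 0.1).
#' @param dispersion Overdispersion: `Var = mu + dispersion * mu^2`.
#' @param roi_area_um2 Fixed ROI area recorded in the table.
#' @param seed RNG seed (required).
#'
#' @return A data frame of class `cell_count_table` with columns
#'   `embryo_id`, `stage`, `half`, `roi_area_um2`, `n_nuclei`; one anterior
#'   and one posterior row per (embryo, stage).
#' @examples
#' cc <- simulate_cell_counts(n_embryos = 3, stages = 8:12, seed = 1)
#' head(cc)
#' @export
simulate_cell_counts <- function(n_embryos = 5, stages = 5:15,
                                 baseline_density = 100,
                                 contrast_by_stage = NULL, onset_stage = 10,
                                 contrast_step = 0.1, dispersion = 0.05,
                                 roi_area_um2 = 2500, seed) {
  if (length(stages) == 0) stop_input("simulate_cell_counts: empty stage range")
  if (!is_count(n_embryos) || baseline_density <= 0) {
    stop_input("simulate_cell_counts: n_embryos and baseline_density must be positive")
  }
  if (missing(seed) || is.null(seed)) {
    stop_input("simulate_cell_counts: seed is required")
  }
  ratio <- if (is.null(contrast_by_stage)) {
    stats::setNames(ifelse(stages < onset_stage, 1,
                           1 + contrast_step * (stages - onset_stage + 1)),
                    stages)
  } else {
    if (!all(as.character(stages) %in% names(contrast_by_stage))) {
      stop_input("simulate_cell_counts: contrast_by_stage must name every stage")
    }
    contrast_by_stage[as.character(stages)]
  }
  if (any(ratio <= 0)) stop_input("simulate_cell_counts: ratios must be positive")

  draw <- function(n, mu) {
    if (dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  tab <- local_seed(seed, {
    rows <- expand.grid(embryo = seq_len(n_embryos), stage = stages,
                        KEEP.OUT.ATTRS = FALSE)
    ant <- draw(nrow(rows), baseline_density)
    post <- draw(nrow(rows), baseline_density * ratio[as.character(rows$stage)])
    data.frame(
      embryo_id = rep(sprintf("embryo%02d", rows$embryo), 2L),
      stage = rep(rows$stage, 2L),
      half = rep(c("anterior", "posterior"), each = nrow(rows)),
      roi_area_um2 = roi_area_um2,
      n_nuclei = c(ant, post))
  })
  tab <- tab[order(tab$embryo_id, tab$stage, tab$half), ]
  rownames(tab) <- NULL
  attr(tab, "seed") <- seed
  attr(tab, "contrast") <- ratio
  class(tab) <- c("cell_count_table", "data.frame")
  tab
}
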