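# From raw approach curve to apparent reduced modulus K:
# baseline correction -> contact point -> indentation -> Hertz fit.

#' Subtract a linear baseline from the pre-contact deflection
#'
#' Fits a straight line to the deflection over the first
#' `precontact_fraction` of samples (assumed to lie before contact) and
#' subtracts it from the whole curve, removing offset and drift so the
#' pre-contact deflection has mean ~0. Idempotent up to numerical noise.
#'
#' @param curve A `force_curve`.
#' @param precontact_fraction Fraction of leading samples used for the fit
#'   (`0 < f <= 0.8`); the window must hold at least 8 samples.
#' @return The curve with corrected deflection; the fitted intercept/slope
#'   are attached as the `baseline` attribute.
#' @export
correct_baseline <- function(curve, precontact_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  if (precontact_fraction <= 0 || precontact_fraction > 0.8) {
    stop_input("correct_baseline: precontact_fraction must lie in (0, 0.8]")
  }
  n <- length(curve$piezo_z_um)
  w <- seq_len(floor(precontact_fraction * n))
  if (length(w) < 8) {
    stop_input("correct_baseline: pre-contact window holds %d samples, need >= 8",
               length(w))
  }
  co <- stats::coef(stats::lm.fit(cbind(1, curve$piezo_z_um[w]),
                                  curve$deflection_um[w]))
  curve$deflection_um <- curve$deflection_um - (co[1] + co[2] * curve$piezo_z_um)
  attr(curve, "baseline") <- c(intercept = unname(co[1]), slope = unname(co[2]))
  curve
}

#' Locate the contact point of an approach curve
#'
#' Scans every admissible sample position as a candidate contact point and
#' scores it with the least-squares residual of a piecewise model: a linear
#' baseline before the candidate and the same baseline plus a Hertzian
#' `F = K * (4/3) * sqrt(R) * delta^(3/2)` rise after it (with
#' `delta = (z - z_cand) - (d - d_cand)`). For each candidate the baseline
#' (intercept and slope) and K are profiled out by one linear fit over the
#' whole curve, so residual baseline offset or drift cannot masquerade as a
#' contact shift; the candidate minimizing the residual wins. The scan is
#' deterministic, exact on noise-free curves, and equivariant under piezo
#' translation and deflection offset.
#'
#' @param curve A `force_curve`; baseline correction beforehand is allowed
#'   but not required, since the scan profiles the baseline itself.
#' @param min_pre,min_post Minimum samples required on each side of a
#'   candidate.
#' @param noise_mult Contact is declared absent (an error) when no
#'   deflection rises more than `noise_mult` baseline-residual SDs above
#'   the leading quarter's trend line.
#' @return An object of class `contact_point`: list with `contact_z_um`,
#'   `contact_index`, `method`, `K_scan_Pa` (the scan's modulus at the
#'   optimum, a diagnostic), `baseline_um` (profiled intercept/slope of
#'   the deflection baseline) and the full `objective_profile` (candidate
#'   index, z, residual) for inspection.
#' @export
find_contact_point <- function(curve, min_pre = 8L, min_post = 8L,
                               noise_mult = 6) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$piezo_z_um
  d <- curve$deflection_um
  n <- length(z)
  if (n < min_pre + min_post + 2L) {
    stop_input("find_contact_point: curve too short (%d samples)", n)
  }
  lead <- seq_len(max(8L, floor(n / 4)))
  co <- stats::coef(stats::lm.fit(cbind(1, z[lead]), d[lead]))
  rel <- d - (co[1] + co[2] * z)
  sd_pre <- stats::sd(rel[lead])
  floor_um <- max(noise_mult * sd_pre, 1e-5)
  if (max(rel) < floor_um) {
    stop_input("find_contact_point: curve never leaves the noise floor (max deflection %.3g um < %.3g um above baseline)",
               max(rel), floor_um)
  }

  k_c <- curve$probe$spring_constant
  R <- curve$probe$bead_radius_um
  f_all <- deflection_to_force_nN(d, k_c)
  pref <- (4 / 3) * sqrt(R * 1e-6)
  candidates <- seq.int(min_pre, n - min_post)
  rss <- rep(Inf, length(candidates))
  K_hat <- rep(NA_real_, length(candidates))
  ab <- matrix(NA_real_, length(candidates), 2L)
  x <- numeric(n)
  for (j in seq_along(candidates)) {
    i0 <- candidates[j]
    post <- (i0 + 1L):n
    delta <- pmax((z[post] - z[i0]) - (d[post] - d[i0]), 0)
    x[] <- 0
    x[post] <- pref * delta^1.5
    if (all(x == 0)) next
    fit <- stats::lm.fit(cbind(1, z, x), f_all)
    K <- fit$coefficients[3]
    if (!is.finite(K) || K <= 0) next
    rss[j] <- sum(fit$residuals^2)
    K_hat[j] <- K
    ab[j, ] <- fit$coefficients[1:2]
  }
  if (all(!is.finite(rss))) {
    stop_input("find_contact_point: no candidate contact position admits a Hertzian rise")
  }
  best <- which.min(rss)
  structure(list(contact_z_um = z[candidates[best]],
                 contact_index = candidates[best],
                 method = "piecewise-hertz-scan",
                 K_scan_Pa = K_hat[best],
                 baseline_um = c(intercept = ab[best, 1] / (1000 * k_c),
                                 slope = ab[best, 2] / (1000 * k_c)),
                 objective_profile = data.frame(index = candidates,
                                                z_um = z[candidates],
                                                rss = rss)),
            class = "contact_point")
}

#' @export
print.contact_point <- function(x, ...) {
  cat(sprintf("Contact point at z = %.4f um (sample %d, %s)\n",
              x$contact_z_um, x$contact_index, x$method))
  invisible(x)
}

#' Convert a force curve past contact into indentation vs force
#'
#' Computes the indentation depth `delta = z - d` measured from the contact
#' point: `delta_i = (z_i - z_c) - (d_i - d_c)`, with the deflection at
#' contact subtracted so that `delta = 0`, `force = 0` at contact. Force is
#' the cantilever restoring force `k_c * (d - d_c)` in nN. Pre-contact
#' samples are excluded.
#'
#' @param curve A baseline-corrected `force_curve`.
#' @param contact A `contact_point` from [find_contact_point()].
#' @return An object of class `indentation_curve`: data frame with
#'   `delta_um` and `force_nN`, plus `source_curve_id` and `probe`
#'   attributes.
#' @export
compute_indentation <- function(curve, contact) {
  stopifnot(inherits(curve, "force_curve"), inherits(contact, "contact_point"))
  z <- curve$piezo_z_um
  i0 <- contact$contact_index
  if (i0 < 1L || i0 > length(z) ||
      abs(z[i0] - contact$contact_z_um) > 1e-9 + diff(range(z)) / length(z)) {
    stop_input("compute_indentation: contact point not within the curve")
  }
  if (i0 >= length(z)) stop_input("compute_indentation: no samples after contact")
  idx <- i0:length(z)
  d_rel <- curve$deflection_um[idx] - curve$deflection_um[i0]
  out <- data.frame(delta_um = (z[idx] - z[i0]) - d_rel,
                    force_nN = deflection_to_force_nN(d_rel,
                                                      curve$probe$spring_constant))
  attr(out, "source_curve_id") <- curve$curve_id
  attr(out, "probe") <- curve$probe
  attr(out, "contact_z_um") <- contact$contact_z_um
  class(out) <- c("indentation_curve", "data.frame")
  out
}

#' Fit the Hertz contact model to an indentation curve
#'
#' Least-squares estimate of the apparent reduced modulus K in
#' `F = (4/3) * K * sqrt(R) * delta^(3/2)` over the contact portion up to
#' `max_force_nN` (default: the 3 nN set force, mirroring the acquisition
#' trigger). With the contact point fixed the estimate is the closed form
#' `K = sum(F_i x_i) / sum(x_i^2)` with `x_i = (4/3) sqrt(R) delta_i^(3/2)`;
#' `refine_contact = TRUE` additionally optimizes a small indentation
#' offset by 1-D search.
#'
#' The Hertz small-indentation assumption (`delta << R`) is violated for
#' very soft samples at this set force; `hertz_small_indentation` flags
#' fits with `max(delta)/R > 0.3` so consumers can treat K as apparent.
#'
#' @param ind An `indentation_curve`.
#' @param bead_radius_um Probe radius in um (default: from the curve's
#'   probe metadata).
#' @param max_force_nN Upper force bound of the fit range in nN.
#' @param refine_contact Logical; jointly refine a contact offset.
#' @param min_points Minimum points in the fit range.
#' @return An object of class `hertz_fit`: `K_Pa`, `contact_z_um`, `rss`
#'   (nN^2), `n_points_fit`, `fit_max_force_nN`, `converged`,
#'   `delta_max_um`, `hertz_small_indentation`, `curve_id`. A negative K
#'   estimate is returned with `converged = FALSE`, never dropped.
#' @export
fit_hertz <- function(ind, bead_radius_um = NULL, max_force_nN = 3,
                      refine_contact = FALSE, min_points = 5L) {
  stopifnot(inherits(ind, "indentation_curve"))
  if (is.null(bead_radius_um)) bead_radius_um <- attr(ind, "probe")$bead_radius_um
  sel <- ind$force_nN <= max_force_nN
  delta <- ind$delta_um[sel]
  f <- ind$force_nN[sel]
  if (length(delta) < min_points) {
    stop_input("fit_hertz: only %d points at or below %g nN, need >= %d",
               length(delta), max_force_nN, min_points)
  }
  if (all(abs(delta) < 1e-12)) {
    stop_input("fit_hertz: all-zero indentation, nothing to fit")
  }
  pref <- (4 / 3) * sqrt(bead_radius_um * 1e-6)
  solve_K <- function(offset) {
    x <- pref * pmax(delta - offset, 0)^1.5
    sxx <- sum(x * x)
    if (sxx == 0) return(list(K = NA_real_, rss = Inf))
    K <- sum(f * x) / sxx
    list(K = K, rss = sum((f - K * x)^2))
  }
  offset <- 0
  if (refine_contact) {
    span <- max(diff(ind$delta_um[seq_len(min(5L, nrow(ind)))]), 1e-3)
    opt <- stats::optimize(function(o) solve_K(o)$rss,
                           interval = c(-2 * span, 2 * span))
    offset <- opt$minimum
  }
  est <- solve_K(offset)
  converged <- is.finite(est$K) && est$K > 0
  structure(list(K_Pa = est$K,
                 contact_z_um = attr(ind, "contact_z_um"),
                 rss = est$rss,
                 n_points_fit = length(delta),
                 fit_max_force_nN = max_force_nN,
                 converged = converged,
                 delta_max_um = max(delta),
                 hertz_small_indentation = max(delta) / bead_radius_um <= 0.3,
                 contact_offset_um = offset,
                 curve_id = attr(ind, "source_curve_id")),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit%s: K = %.4g Pa (%d points <= %g nN, rss %.3g nN^2)%s\n",
              if (is.null(x$curve_id)) "" else paste0(" [", x$curve_id, "]"),
              x$K_Pa, x$n_points_fit, x$fit_max_force_nN, x$rss,
              if (x$converged) "" else " NOT CONVERGED"))
  if (!x$hertz_small_indentation) {
    cat("  note: max indentation exceeds 0.3 R; K is an apparent modulus\n")
  }
  invisible(x)
}

#' Process one force curve to a Hertz fit
#'
#' Convenience chain: [find_contact_point()] -> subtract the scan's
#' profiled baseline -> [compute_indentation()] -> [fit_hertz()]. The
#' contact scan estimates the linear deflection baseline jointly with the
#' contact position, so no separate [correct_baseline()] pass is needed
#' (running one first is harmless). Failures at any stage yield a
#' non-converged result with `K_Pa = NA` (and the failure message), never
#' an error, so batch runs complete with missing values in place.
#'
#' @param curve A `force_curve`.
#' @param max_force_nN Fit range bound; default the probe's set force.
#' @param ... Passed to [fit_hertz()].
#' @return A `hertz_fit` (possibly non-converged).
#' @export
process_curve <- function(curve,
                          max_force_nN = curve$probe$set_force_nN, ...) {
  tryCatch({
    cp <- find_contact_point(curve)
    curve$deflection_um <- curve$deflection_um -
      (cp$baseline_um[["intercept"]] + cp$baseline_um[["slope"]] * curve$piezo_z_um)
    ind <- compute_indentation(curve, cp)
    fit_hertz(ind, max_force_nN = max_force_nN, ...)
  }, error = function(e) {
    structure(list(K_Pa = NA_real_, contact_z_um = NA_real_, rss = NA_real_,
                   n_points_fit = 0L, fit_max_force_nN = max_force_nN,
                   converged = FALSE, delta_max_um = NA_real_,
                   hertz_small_indentation = NA, contact_offset_um = NA_real_,
                   curve_id = curve$curve_id,
                   error = conditionMessage(e)),
              class = "hertz_fit")
  })
}

#' Fit every curve of a bundle
#'
#' Applies [process_curve()] to each curve and collects the per-curve
#' results into the flat table consumed by [assemble_map()].
#'
#' @param bundle A `force_bundle` (or plain list of `force_curve`s).
#' @param ... Passed to [process_curve()].
#' @return A data frame of class `curve_fits` with columns `curve_id`,
#'   `grid_x_um`, `grid_y_um`, `K_Pa`, `contact_z_um`, `rss`,
#'   `n_points_fit`, `converged`, `hertz_small_indentation`.
#' @export
fit_grid <- function(bundle, ...) {
  fits <- lapply(bundle, function(fc) {
    ft <- process_curve(fc, ...)
    data.frame(curve_id = fc$curve_id, grid_x_um = fc$grid_x_um,
               grid_y_um = fc$grid_y_um, K_Pa = ft$K_Pa,
               contact_z_um = ft$contact_z_um, rss = ft$rss,
               n_points_fit = ft$n_points_fit, converged = ft$converged,
               hertz_small_indentation = isTRUE(ft$hertz_small_indentation))
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  class(out) <- c("curve_fits", "data.frame")
  out
}
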