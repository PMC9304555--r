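# Sinusoidal regression of the A/P stiffness profile:
# y(t) = C + alpha * sin(omega * t + phi).

#' Starting values for the sinusoid fit
#'
#' The initialization scheme of the periodicity analysis:
#' `C0 = (max(y) + min(y)) / 2`, `alpha0 = max(y) - C0`,
#' `omega0 = 2 * pi / segment_length_points` (one stiffness period per
#' somite segment), and phase candidates `phi0 = 0` for a profile starting
#' with a posterior half-sclerotome, `phi0 = pi` for one starting anterior,
#' or both when the half-order is unknown.
#'
#' @param profile An `ap_profile` (or data frame with `t` and `K_Pa`).
#' @param segment_length_points Points per somite segment (default 15).
#' @param starts_with `"posterior"`, `"anterior"`, or `"unknown"`.
#' @return An object of class `sinusoid_init` with `C0`, `alpha0`,
#'   `omega0`, `phi0_candidates`.
#' @export
sinusoid_init <- function(profile, segment_length_points = 15,
                          starts_with = c("unknown", "anterior", "posterior")) {
  starts_with <- match.arg(starts_with)
  y <- profile$K_Pa[!is.na(profile$K_Pa)]
  if (length(y) < 2 * segment_length_points) {
    stop_input("sinusoid_init: need >= %d profile points (two segments), got %d",
               2 * segment_length_points, length(y))
  }
  if (max(y) == min(y)) {
    stop_input("sinusoid_init: constant profile, sinusoid initialization is degenerate")
  }
  C0 <- (max(y) + min(y)) / 2
  structure(list(C0 = C0, alpha0 = max(y) - C0,
                 omega0 = 2 * pi / segment_length_points,
                 phi0_candidates = switch(starts_with,
                                          posterior = 0,
                                          anterior = pi,
                                          unknown = c(0, pi)),
                 starts_with = starts_with),
            class = "sinusoid_init")
}

#' Fit the periodic stiffness model by nonlinear least squares
#'
#' Fits `y(t) = C + alpha * sin(omega * t + phi)` to an A/P profile by
#' Levenberg-Marquardt least squares, started from each phase candidate of
#' the initialization; the lowest-RSS solution wins (ties toward
#' `phi0 = 0`). Parameters are canonicalized to `alpha >= 0` and
#' `phi` in `[0, 2*pi)` — the representations `(alpha, phi)` and
#' `(-alpha, phi + pi)` describe the same curve. The goodness-of-fit
#' summary `pearson_R` is the Pearson correlation between fitted and
#' observed values. Missing profile points are dropped from the objective.
#' If no start converges, a non-converged result (not an error) carrying
#' the optimizer diagnostics is returned.
#'
#' @param profile An `ap_profile` (or data frame with `t` and `K_Pa`).
#' @param init A `sinusoid_init`; built from `profile` when `NULL`.
#' @param segment_length_points,starts_with Used to build `init` when it is
#'   not supplied.
#' @param maxiter,ftol Optimizer control: iteration cap and relative
#'   tolerance.
#' @return An object of class `sinusoid_fit`: `C`, `alpha`, `omega`, `phi`,
#'   `rss`, `pearson_R`, `converged`, `n_points`, `init_used`,
#'   `phi0_chosen`.
#' @examples
#' t <- 0:44
#' prof <- data.frame(t = t, K_Pa = 40 + 4 * sin(0.42 * t + pi))
#' fit_sinusoid(prof)
#' @export
fit_sinusoid <- function(profile, init = NULL, segment_length_points = 15,
                         starts_with = "unknown", maxiter = 200,
                         ftol = 1e-8) {
  ok <- !is.na(profile$K_Pa)
  t <- profile$t[ok]
  y <- profile$K_Pa[ok]
  if (length(y) < 8) {
    stop_input("fit_sinusoid: need >= 8 non-missing profile points, got %d",
               length(y))
  }
  if (is.null(init)) {
    init <- sinusoid_init(profile, segment_length_points, starts_with)
  }
  dat <- data.frame(t = t, y = y)
  runs <- lapply(init$phi0_candidates, function(phi0) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ C + alpha * sin(omega * t + phi), data = dat,
        start = list(C = init$C0, alpha = init$alpha0,
                     omega = init$omega0, phi = phi0),
        control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol))
      list(ok = TRUE, phi0 = phi0, fit = fit,
           rss = sum(stats::resid(fit)^2))
    }, error = function(e) list(ok = FALSE, phi0 = phi0,
                                message = conditionMessage(e)))
  })
  good <- Filter(function(r) r$ok, runs)
  if (length(good) == 0) {
    return(structure(list(C = NA_real_, alpha = NA_real_, omega = NA_real_,
                          phi = NA_real_, rss = NA_real_,
                          pearson_R = NA_real_, converged = FALSE,
                          n_points = length(y), init_used = init,
                          phi0_chosen = NA_real_,
                          diagnostics = vapply(runs, function(r)
                            if (r$ok) "" else r$message, character(1))),
                     class = "sinusoid_fit"))
  }
  # lower RSS wins; ties (within fp noise) toward phi0 = 0
  rsss <- vapply(good, function(r) r$rss, numeric(1))
  best <- good[[which.min(rsss)]]
  p <- stats::coef(best$fit)
  C <- unname(p["C"]); alpha <- unname(p["alpha"])
  omega <- unname(p["omega"]); phi <- unname(p["phi"])
  if (alpha < 0) {           # canonical representation
    alpha <- -alpha
    phi <- phi + pi
  }
  if (omega < 0) {           # sin(-w t + p) = sin(w t + (pi - p)) reflected
    omega <- -omega
    phi <- pi - phi
  }
  phi <- phi %% (2 * pi)
  yhat <- stats::fitted(best$fit)
  structure(list(C = C, alpha = alpha, omega = omega, phi = phi,
                 rss = best$rss,
                 pearson_R = stats::cor(as.numeric(yhat), y),
                 converged = TRUE, n_points = length(y),
                 init_used = init, phi0_chosen = best$phi0),
            class = "sinusoid_fit")
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Sinusoid fit: NOT CONVERGED from any phase start\n")
    return(invisible(x))
  }
  cat(sprintf("Sinusoid fit over %d points: y(t) = %.3f + %.3f * sin(%.4f t + %.3f)\n",
              x$n_points, x$C, x$alpha, x$omega, x$phi))
  cat(sprintf("  RSS = %.4g Pa^2, Pearson R (fitted vs observed) = %.3f\n",
              x$rss, x$pearson_R))
  invisible(x)
}

#' Summarize periodicity fits across somite strips
#'
#' Arithmetic mean and SD of the fitted angular frequency `omega` and of
#' the Pearson fit correlation R across strips (one fit per strip /
#' embryo), treating strips as exchangeable replicates. Non-converged fits
#' are excluded and counted. A single fit reports `sd = 0`.
#'
#' @param fits A list of `sinusoid_fit` objects.
#' @return An object of class `periodicity_summary`: `omega_mean`,
#'   `omega_sd`, `R_mean`, `R_sd`, `n`, `n_excluded`.
#' @export
periodicity_summary <- function(fits) {
  if (inherits(fits, "sinusoid_fit")) fits <- list(fits)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) {
    stop_input("periodicity_summary: no converged fits to summarize")
  }
  omega <- vapply(conv, function(f) f$omega, numeric(1))
  R <- vapply(conv, function(f) f$pearson_R, numeric(1))
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  structure(list(omega_mean = mean(omega), omega_sd = sd0(omega),
                 R_mean = mean(R), R_sd = sd0(R),
                 n = length(conv), n_excluded = length(fits) - length(conv)),
            class = "periodicity_summary")
}

#' @export
print.periodicity_summary <- function(x, ...) {
  cat(sprintf("Periodicity across %d strip(s)%s:\n", x$n,
              if (x$n_excluded) sprintf(" (%d non-converged excluded)", x$n_excluded) else ""))
  cat(sprintf("  omega = %.3f +/- %.3f rad/point\n", x$omega_mean, x$omega_sd))
  cat(sprintf("  Pearson R = %.2f +/- %.2f\n", x$R_mean, x$R_sd))
  invisible(x)
}
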