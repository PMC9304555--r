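# Ground-truth stiffness fields for synthetic somite strips.

#' Construct a periodic ground-truth stiffness field
#'
#' Builds the true apparent reduced modulus `K` on a raster grid whose
#' antero-posterior (A/P) axis carries one stiffness period per somite
#' segment. Two spatial profiles are supported:
#' \describe{
#'   \item{`"sinusoid"`}{`K(row, col) = C + alpha * sin(omega * t + phase)`
#'     with the 0-based column coordinate `t = col - 1` and
#'     `omega = 2 * pi / segment_length_points` (unless overridden),
#'     identical across dorso-ventral rows.}
#'   \item{`"square"`}{two levels by half label: `C + alpha` on posterior
#'     halves and `C - alpha` on anterior halves, so the half means equal
#'     those levels exactly.}
#' }
#' Optional i.i.d. Gaussian stiffness noise (`k_noise_sd`, Pa) is added per
#' grid point. Phase follows the half-order convention of the periodicity
#' fit: `phase = 0` for a strip starting with a posterior half-sclerotome,
#' `phase = pi` for one starting anterior.
#'
#' @param C_true Mean stiffness level in Pa (must exceed `alpha_true` so K
#'   stays positive).
#' @param alpha_true Modulation amplitude in Pa (>= 0).
#' @param segment_length_points Points per somite segment along A/P
#'   (default 15, i.e. one segment per 15 raster steps).
#' @param n_segments Number of full segments.
#' @param n_rows_DV Number of dorso-ventral rows.
#' @param phase Phase in radians (`0` or `pi` select the half-order
#'   convention; other values allowed).
#' @param seed RNG seed; required when `k_noise_sd > 0`.
#' @param profile `"sinusoid"` (default) or `"square"`.
#' @param omega Angular frequency in rad/point; defaults to
#'   `2 * pi / segment_length_points`. Half labels always follow the integer
#'   segment length.
#' @param k_noise_sd Per-point Gaussian noise on K, in Pa.
#' @param step_um Grid spacing in micrometres (default 15).
#' @param first_stage Somite stage of the first segment (default VIII).
#'
#' @return An object of class `truth_field`: a list with the `K_true` matrix
#'   (rows = D/V, cols = A/P), `step_um`, `segment_length_points`,
#'   `half_labels` per column, `segments` annotation (with roman-numeral
#'   stages), `params = c(C, alpha, omega, phase)`, `profile` and `seed`.
#' @examples
#' tf <- make_truth_field(40, 4, n_segments = 3, n_rows_DV = 3)
#' dim(tf$K_true)       # 3 x 45
#' tf$params[["omega"]] # 2*pi/15
#' @export
make_truth_field <- function(C_true, alpha_true, segment_length_points = 15,
                             n_segments = 3, n_rows_DV = 3, phase = 0,
                             seed = NULL, profile = c("sinusoid", "square"),
                             omega = NULL, k_noise_sd = 0, step_um = 15,
                             first_stage = 8L) {
  profile <- match.arg(profile)
  if (!(alpha_true >= 0 && C_true > alpha_true)) {
    stop_input(paste0("make_truth_field: need C_true > alpha_true >= 0 to keep K ",
                      "positive (got C_true = %g, alpha_true = %g)"),
               C_true, alpha_true)
  }
  if (!is_count(n_segments) || !is_count(n_rows_DV) ||
      !is_count(segment_length_points)) {
    stop_input("make_truth_field: counts must be positive integers")
  }
  if (k_noise_sd > 0 && is.null(seed)) {
    stop_input("make_truth_field: seed is required when k_noise_sd > 0")
  }
  L <- as.integer(segment_length_points)
  n_cols <- L * as.integer(n_segments)
  if (is.null(omega)) omega <- 2 * pi / L
  t <- seq_len(n_cols) - 1

  # Half-order from the phase convention: does the strip open posterior-high?
  first_half <- seq_len(max(1L, floor(L / 2)))
  starts_with <- if (mean(sin(omega * (first_half - 1) + phase)) > 0) {
    "posterior"
  } else {
    "anterior"
  }
  segs <- assign_halves(n_cols, L, starts_with = starts_with,
                        first_stage = first_stage)
  labels <- half_labels(segs, n_cols)

  k_col <- switch(profile,
    sinusoid = C_true + alpha_true * sin(omega * t + phase),
    square = ifelse(labels == "posterior", C_true + alpha_true,
                    C_true - alpha_true)
  )
  K <- matrix(rep(k_col, each = n_rows_DV), nrow = n_rows_DV)
  if (k_noise_sd > 0) {
    K <- K + local_seed(seed,
      matrix(stats::rnorm(length(K), sd = k_noise_sd), nrow = n_rows_DV))
  }
  if (any(K <= 0)) {
    stop_input(paste0("make_truth_field: parameters yield non-positive K ",
                      "(C_true = %g, alpha_true = %g, k_noise_sd = %g)"),
               C_true, alpha_true, k_noise_sd)
  }
  segs$stage_roman <- as.character(utils::as.roman(segs$stage))
  structure(list(K_true = K, step_um = step_um,
                 segment_length_points = L,
                 half_labels = labels, segments = segs,
                 params = c(C = C_true, alpha = alpha_true,
                            omega = omega, phase = phase),
                 profile = profile, k_noise_sd = k_noise_sd,
                 starts_with = starts_with, seed = seed),
            class = "truth_field")
}

#' @export
print.truth_field <- function(x, ...) {
  cat(sprintf("Synthetic stiffness field (%s): %d x %d grid, step %g um\n",
              x$profile, nrow(x$K_true), ncol(x$K_true), x$step_um))
  cat(sprintf("  C = %g Pa, alpha = %g Pa, omega = %.4f rad/point, phase = %.3f\n",
              x$params[["C"]], x$params[["alpha"]], x$params[["omega"]],
              x$params[["phase"]]))
  cat(sprintf("  %d segments of %d points, starts %s, K noise sd %g Pa\n",
              nrow(x$segments), x$segment_length_points, x$starts_with,
              x$k_noise_sd))
  invisible(x)
}
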