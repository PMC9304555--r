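#' AFM probe description
#'
#' Bundles the cantilever and bead parameters needed to convert deflections
#' to forces and to evaluate the Hertz sphere-on-half-space contact model.
#' Defaults describe a tipless soft cantilever (spring constant 0.035 N/m)
#' carrying a 37 um diameter polystyrene bead (radius 18.5 um), driven to a
#' 3 nN set force at 10 um/s.
#'
#' @param spring_constant Cantilever spring constant in N/m.
#' @param bead_radius_um Radius of the spherical probe in micrometres.
#' @param set_force_nN Trigger force in nN at which the approach stops.
#' @param approach_speed_um_s Approach speed in um/s (metadata only; the
#'   analysis is quasi-static).
#'
#' @return An object of class `probe_spec`.
#' @examples
#' probe_spec()
#' probe_spec(spring_constant = 0.03)
#' @export
probe_spec <- function(spring_constant = 0.035, bead_radius_um = 18.5,
                       set_force_nN = 3.0, approach_speed_um_s = 10) {
  vals <- c(spring_constant = spring_constant, bead_radius_um = bead_radius_um,
            set_force_nN = set_force_nN, approach_speed_um_s = approach_speed_um_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop_input("probe_spec: all parameters must be strictly positive (offending: %s)",
               paste(bad, collapse = ", "))
  }
  structure(list(spring_constant = spring_constant,
                 bead_radius_um = bead_radius_um,
                 set_force_nN = set_force_nN,
                 approach_speed_um_s = approach_speed_um_s),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat("AFM probe:\n")
  cat(sprintf("  spring constant : %.4g N/m\n", x$spring_constant))
  cat(sprintf("  bead radius     : %.4g um\n", x$bead_radius_um))
  cat(sprintf("  set force       : %.4g nN\n", x$set_force_nN))
  cat(sprintf("  approach speed  : %.4g um/s\n", x$approach_speed_um_s))
  invisible(x)
}
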