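# Hertz sphere-on-half-space contact mechanics and unit conversions.
# Unit conventions, centralized here: lengths in um, spring constant in N/m,
# force in nN, moduli in Pa. 1 N/m x 1 um = 1000 nN.

# Hertz prefactor in nN / um^(3/2): F_nN = A * delta_um^(3/2).
# Derivation: F = (4/3) K sqrt(R_m) delta_m^(3/2) with delta_m = delta_um*1e-6,
# so F_nN = (4/3) K sqrt(R_um*1e-6) delta_um^(3/2) (the 1e-9 from delta^{3/2}
# cancels the N -> nN factor 1e9).
hertz_prefactor <- function(K_Pa, bead_radius_um) {
  (4 / 3) * K_Pa * sqrt(bead_radius_um * 1e-6)
}

# Cantilever deflection (um) to force (nN).
deflection_to_force_nN <- function(deflection_um, spring_constant) {
  1000 * spring_constant * deflection_um
}

#' Hertz contact force for a sphere indenting an elastic half-space
#'
#' Evaluates `F = (4/3) * K * sqrt(R) * delta^(3/2)` for a rigid sphere of
#' radius `R` pressed a depth `delta` into a flat elastic half-space of
#' apparent reduced modulus `K = E / (1 - v^2)`.
#'
#' @param delta_um Indentation depth in micrometres (must be >= 0).
#' @param K_Pa Apparent reduced elastic modulus in Pa.
#' @param bead_radius_um Sphere radius in micrometres.
#'
#' @return Force in nN, the same length as `delta_um`.
#' @examples
#' hertz_force(1, K_Pa = 40, bead_radius_um = 18.5)  # ~0.229 nN
#' @seealso [hertz_indentation()] for the inverse, [reduced_modulus()].
#' @export
hertz_force <- function(delta_um, K_Pa, bead_radius_um) {
  if (any(delta_um < 0)) {
    stop_input("hertz_force: indentation depth must be non-negative")
  }
  stopifnot(K_Pa > 0, bead_radius_um > 0)
  hertz_prefactor(K_Pa, bead_radius_um) * delta_um^1.5
}

#' Indentation depth reaching a given Hertz contact force
#'
#' Closed-form inverse of [hertz_force()]:
#' `delta = (F / ((4/3) K sqrt(R)))^(2/3)`.
#'
#' @param force_nN Force in nN (must be >= 0).
#' @inheritParams hertz_force
#' @return Indentation depth in micrometres.
#' @examples
#' hertz_indentation(3, K_Pa = 40, bead_radius_um = 18.5)  # ~5.6 um
#' @export
hertz_indentation <- function(force_nN, K_Pa, bead_radius_um) {
  if (any(force_nN < 0)) {
    stop_input("hertz_indentation: force must be non-negative")
  }
  (force_nN / hertz_prefactor(K_Pa, bead_radius_um))^(2 / 3)
}

#' Apparent reduced elastic modulus
#'
#' `K = E / (1 - v^2)`: the stiffness measure reported by spherical AFM
#' indentation without committing to a Poisson ratio.
#'
#' @param E_Pa Young's modulus in Pa.
#' @param poisson_ratio Poisson's ratio `v`, with `0 <= v < 1`.
#' @return Reduced modulus in Pa.
#' @examples
#' reduced_modulus(30, 0.5)  # 40 Pa
#' @export
reduced_modulus <- function(E_Pa, poisson_ratio) {
  if (any(poisson_ratio < 0) || any(poisson_ratio >= 1)) {
    stop_input("reduced_modulus: poisson_ratio must lie in [0, 1)")
  }
  E_Pa / (1 - poisson_ratio^2)
}
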