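#' Single-term chain potentials
#'
#' Closed-form evaluation of the three bonded interaction terms.
#' `morse_energy` is the anharmonic bond potential
#' \eqn{D (1 - e^{-\alpha(r - r_0)})^2}, bounded by the dissociation energy
#' `D` as `r` grows, which is what lets bonds break.  `bend_energy` is the
#' harmonic angle term \eqn{\frac12 K (\theta - \theta_0)^2}.
#' `torsion_energy` is the cosine series \eqn{\sum_c K_c \cos^{c-1}\phi},
#' periodic and even in `phi`.
#'
#' @param r bond length(s), Angstrom; must be > 0.
#' @param D,alpha,r0 Morse parameters (kcal/mol, 1/A, A).
#' @return energy in kcal/mol, vectorized over the first argument.
#' @export
morse_energy <- function(r, D, alpha, r0) {
  if (any(r <= 0)) stop("bond length r must be > 0")
  e <- exp(-alpha * (r - r0))
  D * (1 - e)^2
}

#' @param theta bend angle(s), rad, in [0, pi].
#' @param K,theta0 bend force constant (kcal/mol/rad^2) and equilibrium angle.
#' @rdname morse_energy
#' @export
bend_energy <- function(theta, K, theta0) {
  if (any(theta < 0 | theta > pi)) stop("bend angle must lie in [0, pi]")
  0.5 * K * (theta - theta0)^2
}

#' @param phi dihedral angle(s), rad.
#' @param K_list numeric vector of cosine-series coefficients K_c, c = 1..C
#'   (K_1 multiplies cos^0 = 1); an empty vector gives 0.
#' @rdname morse_energy
#' @export
torsion_energy <- function(phi, K_list) {
  if (length(K_list) == 0) return(rep(0, length(phi)))
  cp <- cos(phi)
  out <- numeric(length(phi))
  pw <- rep(1, length(phi))
  for (c in seq_along(K_list)) {
    out <- out + K_list[c] * pw
    pw <- pw * cp
  }
  out
}

#' Total chain potential energy and forces
#'
#' `chain_potential` sums the Morse bond, harmonic bend and cosine-series
#' torsion terms over the chain; it is invariant under rigid translations
#' and rotations.  `chain_forces` returns the analytic negative gradient,
#' an N x 3 matrix in kcal/mol/A; the rows sum to zero (no net force) and
#' the total torque about the origin vanishes.  When a bend angle is within
#' about 1e-6 rad of 0 or pi, the (undefined) dihedral force contribution
#' at that site is dropped.
#'
#' @param state a `chain_state`.
#' @param ff a `force_field` with matching bead count.
#' @return scalar energy (kcal/mol), or N x 3 force matrix.
#' @export
chain_potential <- function(state, ff) {
  check_state_ff(state, ff)
  cpp_potential(state$positions, ff_as_list(ff))
}

#' @rdname chain_potential
#' @export
chain_forces <- function(state, ff) {
  check_state_ff(state, ff)
  cpp_forces(state$positions, ff_as_list(ff))
}
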