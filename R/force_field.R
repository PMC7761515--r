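#' Bead-spring chain force field
#'
#' Defines a homogeneous united-atom style chain of `n_beads` beads connected
#' by Morse bonds, with harmonic angle bending and a cosine-series torsion
#' potential on each dihedral:
#' \deqn{U_{bond}(r) = D (1 - e^{-\alpha (r - r_0)})^2}
#' \deqn{U_{bend}(\theta) = \tfrac12 K_b (\theta - \theta_0)^2}
#' \deqn{U_{tors}(\phi) = \sum_{c=1}^{C} K^t_c \cos^{c-1}\phi}
#' Non-bonded interactions are deliberately absent (implicit theta solvent).
#' A chain of N beads has N-1 bonds, N-2 bends and N-3 torsions.
#'
#' The default parameters describe a generic stiff chain whose torsion
#' profile is bistable (a trans global minimum and a gauche local minimum
#' separated by a barrier of a few k_B T at 300 K), which is what produces
#' the multi-well stretching phenomenology the transform toolkit diagnoses.
#'
#' @param n_beads integer number of beads, N >= 2.
#' @param masses per-bead mass in g/mol; scalar is recycled.
#' @param bond_D Morse dissociation energy, kcal/mol.
#' @param bond_alpha Morse inverse-length stiffness, 1/Angstrom.
#' @param bond_r0 equilibrium bond length, Angstrom.
#' @param bend_K bending force constant, kcal/mol/rad^2.
#' @param bend_theta0 equilibrium bend angle, rad.
#' @param torsion_K cosine-series coefficients K^t_c (kcal/mol): either a
#'   single numeric vector used for every dihedral, or a list with one
#'   vector per dihedral (length N-3).
#' @return an object of class `force_field`.
#' @examples
#' ff <- force_field(8)
#' ff
#' @export
force_field <- function(n_beads, masses = 14, bond_D = 80, bond_alpha = 2,
                        bond_r0 = 1.5, bend_K = 60, bend_theta0 = 1.9,
                        torsion_K = c(2.0, -2.7, -1.8, 6.0)) {
  n_beads <- as.integer(n_beads)
  if (is.na(n_beads) || n_beads < 2) stop("n_beads must be an integer >= 2")
  if (length(masses) == 1) masses <- rep(masses, n_beads)
  if (length(masses) != n_beads) stop("masses must have length 1 or n_beads")
  n_tors <- max(n_beads - 3L, 0L)
  if (!is.list(torsion_K)) torsion_K <- rep(list(as.numeric(torsion_K)), n_tors)
  if (length(torsion_K) != n_tors)
    stop("torsion_K must supply one coefficient vector per dihedral (", n_tors, ")")
  ff <- structure(list(
    n_beads = n_beads, masses = as.numeric(masses),
    bond_D = as.numeric(bond_D), bond_alpha = as.numeric(bond_alpha),
    bond_r0 = as.numeric(bond_r0), bend_K = as.numeric(bend_K),
    bend_theta0 = as.numeric(bend_theta0),
    torsion_K = lapply(torsion_K, as.numeric)),
    class = "force_field")
  validate_force_field(ff)
  ff
}

validate_force_field <- function(ff) {
  stopifnot(inherits(ff, "force_field"))
  with(ff, {
    if (!(bond_D > 0)) stop("bond_D must be > 0")
    if (!(bond_alpha > 0)) stop("bond_alpha must be > 0")
    if (!(bond_r0 > 0)) stop("bond_r0 must be > 0")
    if (bend_K < 0) stop("bend_K must be >= 0")
    if (any(masses <= 0)) stop("all masses must be > 0")
    if (bend_theta0 < 0 || bend_theta0 > pi) stop("bend_theta0 must lie in [0, pi]")
  })
  invisible(ff)
}

#' @export
print.force_field <- function(x, ...) {
  cat("Bead-spring chain force field\n")
  cat(sprintf("  N = %d beads (%d bonds, %d bends, %d torsions)\n",
              x$n_beads, x$n_beads - 1, max(x$n_beads - 2, 0),
              max(x$n_beads - 3, 0)))
  cat(sprintf("  Morse bond: D = %g kcal/mol, alpha = %g 1/A, r0 = %g A\n",
              x$bond_D, x$bond_alpha, x$bond_r0))
  cat(sprintf("  Bend: K = %g kcal/mol/rad^2, theta0 = %g rad\n",
              x$bend_K, x$bend_theta0))
  if (length(x$torsion_K))
    cat("  Torsion K^t:", paste(signif(x$torsion_K[[1]], 4), collapse = ", "),
        if (length(unique(x$torsion_K)) == 1) "(all dihedrals)\n" else "(first dihedral)\n")
  invisible(x)
}

#' Morse inverse length from harmonic bond stiffness
#'
#' Relates a harmonic stretching constant K_s (the curvature of the bond
#' potential at its minimum, kcal/mol/A^2) to the Morse parameter alpha via
#' `alpha = sqrt(K_s / (2 D))`, so that the Morse well has the same curvature:
#' U''(r0) = 2 D alpha^2 = K_s.  (A rendering of this relation without the
#' square root circulates in the literature; dimensional analysis requires
#' the square-root form used here.)
#'
#' @param K_s harmonic stretching constant, kcal/mol/A^2.
#' @param D Morse dissociation energy, kcal/mol.
#' @return alpha in 1/Angstrom.
#' @export
alpha_from_stiffness <- function(K_s, D) {
  if (any(K_s <= 0) || any(D <= 0)) stop("K_s and D must be > 0")
  sqrt(K_s / (2 * D))
}

#' Read or write a force field as a flat YAML config
#'
#' Schema: top-level keys `n_beads`, `masses`, `bond: {D, alpha, r0}`,
#' `bend: {K, theta0}`, `torsion: {K: [..]}` (a single list applied to every
#' dihedral, or a list of lists, one per dihedral).
#'
#' @param file path to a YAML file.
#' @return `read_force_field` returns a `force_field`; `write_force_field`
#'   returns `file` invisibly.
#' @export
read_force_field <- function(file) {
  y <- yaml::read_yaml(file)
  tors <- y$torsion$K
  if (is.list(tors) && length(tors) && is.list(tors[[1]])) tors <- lapply(tors, unlist)
  else if (is.list(tors) && length(tors) && length(tors[[1]]) > 1) tors <- lapply(tors, unlist)
  else tors <- unlist(tors)
  force_field(n_beads = y$n_beads, masses = unlist(y$masses),
              bond_D = y$bond$D, bond_alpha = y$bond$alpha, bond_r0 = y$bond$r0,
              bend_K = y$bend$K, bend_theta0 = y$bend$theta0,
              torsion_K = tors)
}

#' @param ff a `force_field`.
#' @rdname read_force_field
#' @export
write_force_field <- function(ff, file) {
  validate_force_field(ff)
  y <- list(n_beads = ff$n_beads, masses = ff$masses,
            bond = list(D = ff$bond_D, alpha = ff$bond_alpha, r0 = ff$bond_r0),
            bend = list(K = ff$bend_K, theta0 = ff$bend_theta0),
            torsion = list(K = if (length(unique(ff$torsion_K)) <= 1 &&
                                   length(ff$torsion_K))
              ff$torsion_K[[1]] else ff$torsion_K))
  yaml::write_yaml(y, file)
  invisible(file)
}

# plain list form handed to the compiled code
ff_as_list <- function(ff) {
  validate_force_field(ff)
  list(n_beads = ff$n_beads, masses = ff$masses, bond_D = ff$bond_D,
       bond_alpha = ff$bond_alpha, bond_r0 = ff$bond_r0, bend_K = ff$bend_K,
       bend_theta0 = ff$bend_theta0, torsion_K = ff$torsion_K)
}

# largest bond length before the break monitor trips (alpha (r - r0) = 5)
r_break <- function(ff) ff$bond_r0 + 5 / ff$bond_alpha
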