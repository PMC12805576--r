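## Bonded-term constructors and exact evaluation of the three potential
## forms used by the CG model: harmonic bonds, restricted-bending (ReB)
## angles, and periodic dihedrals. Angles are degrees at the API.

#' Bonded-term constructors
#'
#' The CG force field uses three bonded forms:
#' \itemize{
#'   \item harmonic bond: \eqn{V(r) = \frac12 k_b (r - r_0)^2};
#'   \item restricted-bending (ReB) angle:
#'     \eqn{V(\theta) = \frac12 k_\theta (\cos\theta - \cos\theta_0)^2 /
#'     \sin^2\theta}, which diverges as \eqn{\theta \to 180^\circ} and so
#'     keeps CG triples away from collinearity;
#'   \item periodic dihedral:
#'     \eqn{V(\phi) = k_\phi (1 + \cos(n\phi - \phi_s))}.
#' }
#' Lengths are nm, energies kJ/mol, angles degrees.
#'
#' @param i,j,k,l 1-based bead indices.
#' @param r0 equilibrium bond length (nm), > 0.
#' @param k_b bond force constant (kJ mol^-1 nm^-2), > 0.
#' @param theta0 equilibrium angle (deg), strictly inside (0, 180).
#' @param k_theta angle force constant (kJ/mol), > 0.
#' @param k_phi dihedral amplitude (kJ/mol), >= 0.
#' @param n integer multiplicity, >= 1.
#' @param phi_s phase (deg).
#' @return An object of class `harmonic_bond`, `reb_angle` or
#'   `periodic_dihedral` (all also of class `bonded_term`).
#' @examples
#' harmonic_bond(1, 2, r0 = 0.35, k_b = 5000)
#' reb_angle(1, 2, 3, theta0 = 120, k_theta = 50)
#' periodic_dihedral(1, 2, 3, 4, k_phi = 3, n = 1, phi_s = 0)
#' @name bonded_terms
NULL

#' @rdname bonded_terms
#' @export
harmonic_bond <- function(i, j, r0, k_b) {
  stopifnot(r0 > 0, k_b > 0, i != j)
  structure(list(i = as.integer(i), j = as.integer(j), r0 = r0, k_b = k_b),
            class = c("harmonic_bond", "bonded_term"))
}

#' @rdname bonded_terms
#' @export
reb_angle <- function(i, j, k, theta0, k_theta) {
  stopifnot(theta0 > 0, theta0 < 180, k_theta > 0)
  structure(list(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                 theta0 = theta0, k_theta = k_theta),
            class = c("reb_angle", "bonded_term"))
}

#' @rdname bonded_terms
#' @export
periodic_dihedral <- function(i, j, k, l, k_phi, n, phi_s) {
  stopifnot(n >= 1, n == round(n), k_phi >= 0)
  structure(list(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                 l = as.integer(l), k_phi = k_phi, n = as.integer(n),
                 phi_s = phi_s),
            class = c("periodic_dihedral", "bonded_term"))
}

#' Evaluate bonded potentials and their gradients
#'
#' `bond_energy()`, `reb_angle_energy()` and `dihedral_energy()` evaluate
#' the three bonded forms at given internal coordinates; with
#' `deriv = TRUE` they return the analytic first derivative with respect to
#' the internal coordinate instead (dV/dr in kJ mol^-1 nm^-1; dV/dtheta and
#' dV/dphi in kJ mol^-1 deg^-1).
#'
#' @param term a term built by [harmonic_bond()], [reb_angle()] or
#'   [periodic_dihedral()].
#' @param r bond length(s), nm; must be > 0.
#' @param theta angle(s) in degrees, strictly inside (0, 180) for ReB.
#' @param phi dihedral angle(s) in degrees (any value; the form is
#'   periodic).
#' @param deriv if `TRUE` return the analytic derivative.
#' @return Numeric vector of energies (kJ/mol) or derivatives.
#' @examples
#' b <- harmonic_bond(1, 2, r0 = 0.35, k_b = 5000)
#' bond_energy(b, 0.37)   # 1 kJ/mol
#' a <- reb_angle(1, 2, 3, theta0 = 60, k_theta = 10)
#' reb_angle_energy(a, 90) # 1.25 kJ/mol
#' @name bonded_energy
NULL

#' @rdname bonded_energy
#' @export
bond_energy <- function(term, r, deriv = FALSE) {
  if (any(r <= 0)) stop("invalid geometry: bond length must be > 0",
                        call. = FALSE)
  if (deriv) term$k_b * (r - term$r0) else 0.5 * term$k_b * (r - term$r0)^2
}

#' @rdname bonded_energy
#' @export
reb_angle_energy <- function(term, theta, deriv = FALSE) {
  if (any(theta <= 0 | theta >= 180))
    stop("singularity: ReB angle is defined only strictly inside (0, 180) deg",
         call. = FALSE)
  th <- deg2rad(theta)
  th0 <- deg2rad(term$theta0)
  d <- cos(th) - cos(th0)
  s <- sin(th)
  if (!deriv) return(0.5 * term$k_theta * d^2 / s^2)
  ## dV/dtheta (radians): k * d * (-s * s^2 - d * s * cos) / s^4
  ##   = -k * d * (s^2 + d*cos(th)) / s^3 ; convert to per-degree
  dV <- -term$k_theta * d * (s^2 + d * cos(th)) / s^3
  dV * pi / 180
}

#' @rdname bonded_energy
#' @export
dihedral_energy <- function(term, phi, deriv = FALSE) {
  arg <- deg2rad(term$n * phi - term$phi_s)
  if (!deriv) return(term$k_phi * (1 + cos(arg)))
  (-term$k_phi * term$n * sin(arg)) * pi / 180
}

#' @export
print.bonded_term <- function(x, ...) {
  cls <- class(x)[1]
  desc <- switch(cls,
    harmonic_bond = sprintf("(%d,%d) r0 %.4f nm, k %.5g kJ/mol/nm^2",
                            x$i, x$j, x$r0, x$k_b),
    reb_angle = sprintf("(%d,%d,%d) theta0 %.2f deg, k %.5g kJ/mol",
                        x$i, x$j, x$k, x$theta0, x$k_theta),
    periodic_dihedral = sprintf(
      "(%d,%d,%d,%d) k %.5g kJ/mol, n %d, phase %.1f deg",
      x$i, x$j, x$k, x$l, x$k_phi, x$n, x$phi_s))
  cat(sprintf("<%s> %s\n", cls, desc))
  invisible(x)
}

## Boltzmann densities of the three forms (used by the fixture generator,
## the inversion fitters and round-trip tests). Angles carry the sin(theta)
## configurational Jacobian; bonds and dihedrals do not.
bond_boltzmann_density <- function(term, r, temperature = 300) {
  exp(-bond_energy(term, r) / kBT(temperature))
}
reb_boltzmann_density <- function(term, theta, temperature = 300) {
  sin(deg2rad(theta)) * exp(-reb_angle_energy(term, theta) / kBT(temperature))
}
dihedral_boltzmann_density <- function(term, phi, temperature = 300) {
  exp(-dihedral_energy(term, phi) / kBT(temperature))
}
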