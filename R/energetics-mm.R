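# Molecular-mechanics interaction terms (all-pairs, no cutoff) and the
# SASA nonpolar solvation model.

#' Coulomb constant, kJ mol^-1 Angstrom e^-2
#' @export
COULOMB_CONST <- 1389.35458

#' Poisson-Boltzmann solver configuration
#'
#' Defaults follow the continuum-electrostatics setup used for the
#' LC3C-ATG4B binding energies: solute dielectric 2, solvent dielectric 80,
#' 150 mM ionic strength, fine grid spacing 0.5 Angstrom and a coarse box
#' of 1.5 times the solute long axis (grid focusing). Temperature defaults
#' to the 310 K production temperature.
#'
#' @param eps_solute solute (protein) dielectric constant
#' @param eps_solvent solvent dielectric constant
#' @param ionic_strength mol/L
#' @param temperature K
#' @param fine_spacing fine grid spacing, Angstrom
#' @param coarse_factor coarse box edge as a multiple of the solute long axis
#' @param stern_layer ion-exclusion layer thickness, Angstrom
#' @param solver_tol relative residual stopping tolerance
#' @param max_iter SOR iteration cap
#' @param omega SOR over-relaxation factor
#' @param fine_margin solvent margin around the solute on the fine grid, Angstrom
#' @param coarse_margin minimum solvent margin on the coarse grid, Angstrom
#' @return list of class `pb_config`
#' @export
pb_config <- function(eps_solute = 2, eps_solvent = 80, ionic_strength = 0.150,
                      temperature = 310, fine_spacing = 0.5,
                      coarse_factor = 1.5, stern_layer = 2.0,
                      solver_tol = 1e-6, max_iter = 20000, omega = 1.8,
                      fine_margin = 5, coarse_margin = 10) {
  if (!(eps_solvent > eps_solute && eps_solute >= 1))
    stop("require eps_solvent > eps_solute >= 1")
  if (fine_spacing <= 0) stop("fine_spacing must be > 0")
  if (coarse_factor <= 1) stop("coarse_factor must be > 1")
  structure(list(eps_solute = eps_solute, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, temperature = temperature,
                 fine_spacing = fine_spacing, coarse_factor = coarse_factor,
                 stern_layer = stern_layer, solver_tol = solver_tol,
                 max_iter = max_iter, omega = omega,
                 fine_margin = fine_margin, coarse_margin = coarse_margin),
            class = "pb_config")
}

#' SASA model configuration
#'
#' Defaults follow the nonpolar solvation model used for the binding
#' energies: probe radius 1.4 Angstrom, surface tension 0.0226 kJ/mol/A^2
#' and offset 3.84 kJ/mol.
#'
#' @param probe_radius Angstrom
#' @param gamma surface tension, kJ/mol/A^2
#' @param offset_b kJ/mol
#' @param n_sphere_points quadrature points per atom (deterministic spiral)
#' @return list of class `sasa_config`
#' @export
sasa_config <- function(probe_radius = 1.4, gamma = 0.0226, offset_b = 3.84,
                        n_sphere_points = 960) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 60) stop("n_sphere_points must be >= 60")
  structure(list(probe_radius = probe_radius, gamma = gamma,
                 offset_b = offset_b, n_sphere_points = n_sphere_points),
            class = "sasa_config")
}

check_groups <- function(s, groupA, groupB) {
  groupA <- as.integer(groupA); groupB <- as.integer(groupB)
  if (length(intersect(groupA, groupB)) > 0)
    stop("atom groups overlap")
  if (any(c(groupA, groupB) < 1 | c(groupA, groupB) > n_atoms(s)))
    stop("atom index out of range")
  list(A = groupA, B = groupB)
}

pair_distances <- function(xyzA, xyzB) {
  # nA x nB Euclidean distance matrix
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * tcrossprod(xyzA, xyzB)
  sqrt(pmax(d2, 0))
}

#' Inter-group Coulomb energy (kJ/mol)
#'
#' All-pairs sum f q_i q_j / (eps r_ij) with f = 1389.35458
#' kJ mol^-1 Angstrom e^-2; no distance cutoff.
#'
#' @param s param_structure with charges assigned
#' @param groupA,groupB disjoint atom index vectors (see [atom_select()])
#' @param eps uniform dielectric constant (vacuum = 1)
#' @return energy in kJ/mol
#' @export
coulomb_energy <- function(s, groupA, groupB, eps = 1) {
  g <- check_groups(s, groupA, groupB)
  sum(coulomb_pair_matrix(s, g$A, g$B, eps))
}

coulomb_pair_matrix <- function(s, groupA, groupB, eps = 1) {
  xyz <- coords(s)
  r <- pair_distances(xyz[groupA, , drop = FALSE], xyz[groupB, , drop = FALSE])
  if (any(r == 0)) stop("zero inter-atom distance between groups")
  q <- s$atoms$charge
  COULOMB_CONST * outer(q[groupA], q[groupB]) / (eps * r)
}

#' Inter-group Lennard-Jones energy (kJ/mol)
#'
#' All-pairs 4 eps_ij \[(sigma_ij/r)^12 - (sigma_ij/r)^6\] with
#' Lorentz-Berthelot combination (arithmetic sigma, geometric eps); no
#' cutoff.
#'
#' @inheritParams coulomb_energy
#' @return energy in kJ/mol
#' @export
lj_energy <- function(s, groupA, groupB) {
  g <- check_groups(s, groupA, groupB)
  sum(lj_pair_matrix(s, g$A, g$B))
}

lj_pair_matrix <- function(s, groupA, groupB) {
  xyz <- coords(s)
  r <- pair_distances(xyz[groupA, , drop = FALSE], xyz[groupB, , drop = FALSE])
  if (any(r == 0)) stop("zero inter-atom distance between groups")
  a <- s$atoms
  sig <- outer(a$sigma[groupA], a$sigma[groupB], "+") / 2
  epsij <- sqrt(outer(a$eps[groupA], a$eps[groupB]))
  sr6 <- (sig / r)^6
  4 * epsij * (sr6^2 - sr6)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA over heavy atoms using a deterministic golden-spiral
#' quadrature; hydrogens (radius 0) contribute no area and do not occlude.
#'
#' @param s param_structure with radii assigned
#' @param cfg [sasa_config()]
#' @return list with `total` (A^2) and `per_atom` (A^2, length n_atoms)
#' @export
sasa <- function(s, cfg = sasa_config()) {
  a <- s$atoms
  rad <- ifelse(a$is_heavy, a$radius, 0)
  if (any(rad == 0 & a$is_heavy))
    warning(sum(rad == 0 & a$is_heavy),
            " heavy atom(s) with radius 0; assign parameters first?")
  per_atom <- shrake_rupley(coords(s), rad, cfg$probe_radius,
                            as.integer(cfg$n_sphere_points))
  list(total = sum(per_atom), per_atom = as.numeric(per_atom))
}

#' Nonpolar solvation energy from a surface area
#'
#' Linear SASA model gamma * area + b. Note the offset b cancels in
#' binding-energy differences; it enters only per-species absolute values.
#'
#' @param area A^2
#' @param cfg [sasa_config()]
#' @return kJ/mol
#' @export
nonpolar_energy <- function(area, cfg = sasa_config()) {
  if (any(area < 0)) stop("negative surface area")
  cfg$gamma * area + cfg$offset_b
}

#' Debye screening length (Angstrom)
#'
#' Closed form from CODATA constants:
#' lambda_D = sqrt(eps0 eps_r kB T / (2 NA e^2 I)).
#'
#' @param ionic_strength mol/L
#' @param temperature K
#' @param eps_solvent relative solvent permittivity
#' @export
debye_length <- function(ionic_strength, temperature = 298,
                         eps_solvent = 78.54) {
  e <- 1.602176634e-19; kB <- 1.380649e-23
  NA_ <- 6.02214076e23; eps0 <- 8.8541878128e-12
  lam_m <- sqrt(eps0 * eps_solvent * kB * temperature /
                  (2 * NA_ * e^2 * ionic_strength * 1000))
  lam_m * 1e10
}
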