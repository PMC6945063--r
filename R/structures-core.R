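#' @useDynLib phosbind, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd setNames
#' @importFrom utils read.table write.table head
"_PACKAGE"

# Backbone atom names excluded from the side chain. GLY therefore has no
# side-chain heavy atom at all.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3",
                    "HN", "HA", "HA1", "HA2", "HA3")

#' Construct a parameterized structure from an atom table
#'
#' A `param_structure` is the central container of the package: an ordered
#' atom table carrying coordinates (Angstrom), partial charges (e), radii
#' (Angstrom) and Lennard-Jones parameters, plus chain/residue identity.
#' It is the substrate of all energetics and geometry operations.
#'
#' @param atoms data.frame with columns `serial`, `name`, `elem`, `res_name`,
#'   `res_seq`, `chain_id`, `x`, `y`, `z`; optional `charge`, `radius`,
#'   `eps`, `sigma` (zero-filled when absent).
#' @param title optional description string.
#' @return Object of class `param_structure`.
#' @export
param_structure <- function(atoms, title = "") {
  req <- c("serial", "name", "elem", "res_name", "res_seq", "chain_id",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("charge", "radius", "eps", "sigma"))
    if (is.null(atoms[[col]])) atoms[[col]] <- 0
  atoms$serial <- as.integer(atoms$serial)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$name <- as.character(atoms$name)
  atoms$elem <- toupper(as.character(atoms$elem))
  atoms$res_name <- toupper(as.character(atoms$res_name))
  atoms$chain_id <- as.character(atoms$chain_id)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in atom table (rows ",
         paste(which(!stats::complete.cases(xyz)), collapse = ", "), ")")
  if (any(atoms$radius < 0)) stop("negative atom radius")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_seq, atom name): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  atoms$is_heavy <- atoms$elem != "H"
  atoms$is_sidechain <- !(atoms$name %in% BACKBONE_ATOMS)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "param_structure")
}

#' @export
print.param_structure <- function(x, ...) {
  a <- x$atoms
  cat("param_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain_id, a$res_seq))), "residues,",
      length(unique(a$chain_id)), "chain(s)",
      if (nzchar(x$title)) paste0("  [", x$title, "]") else "", "\n")
  cat("  total charge:", format(sum(a$charge), digits = 6), "e\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s param_structure
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param s param_structure
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace atom coordinates
#' @param s param_structure
#' @param xyz n x 3 matrix, Angstrom
#' @export
set_coords <- function(s, xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atoms(s) || ncol(xyz) != 3)
    stop("coordinate matrix must be ", n_atoms(s), " x 3")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Select atom indices by chain, residue, name and flags
#'
#' Returns a duplicate-free, sorted integer index vector into the atom table.
#' All filters are optional and combined with AND.
#'
#' @param s param_structure
#' @param chain chain identifier(s)
#' @param res_seq residue number(s) (as in the source file, never renumbered)
#' @param res_name 3-letter residue code(s)
#' @param name atom name(s)
#' @param heavy if TRUE keep only non-hydrogen atoms
#' @param sidechain if TRUE keep only side-chain atoms
#' @return integer vector of atom indices
#' @export
atom_select <- function(s, chain = NULL, res_seq = NULL, res_name = NULL,
                        name = NULL, heavy = FALSE, sidechain = FALSE) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(res_seq)) keep <- keep & a$res_seq %in% res_seq
  if (!is.null(res_name)) keep <- keep & a$res_name %in% res_name
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (isTRUE(heavy)) keep <- keep & a$is_heavy
  if (isTRUE(sidechain)) keep <- keep & a$is_sidechain
  which(keep)
}

#' Subset a structure by atom indices
#' @param s param_structure
#' @param idx integer atom indices
#' @export
subset_structure <- function(s, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0) stop("empty atom selection")
  if (any(idx < 1 | idx > n_atoms(s))) stop("atom index out of range")
  param_structure(s$atoms[idx, , drop = FALSE], title = s$title)
}

#' Construct a trajectory
#'
#' Ordered coordinate frames congruent with one `param_structure` topology.
#'
#' @param topology param_structure
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom)
#' @param times frame times in ps, strictly increasing; synthesized from
#'   `timestep_ps` when NULL
#' @param timestep_ps spacing used to synthesize times (default 1)
#' @return Object of class `trajectory`
#' @export
trajectory <- function(topology, frames, times = NULL, timestep_ps = 1) {
  stopifnot(inherits(topology, "param_structure"))
  na <- n_atoms(topology)
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != na || ncol(f) != 3)
      stop("frame ", i, " has ", nrow(f), " atoms; topology has ", na)
    dimnames(f) <- NULL
    f
  })
  if (is.null(times)) times <- (seq_along(frames) - 1) * timestep_ps
  if (length(times) != length(frames))
    stop("times length must equal frame count")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames x", n_atoms(x$topology),
      "atoms, t =", x$times[1], "..", x$times[length(x$times)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory
#' @export
n_frames <- function(traj) length(traj$frames)

# Derive an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, handle leading digits (e.g. "1HB"), two-letter
# ions kept as-is.
element_from_name <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("[0-9']", "", nm)
    if (nchar(nm) == 0) return("X")
    first <- substr(nm, 1, 1)
    if (toupper(nm) %in% c("NA", "CL", "MG", "ZN", "CA2", "FE", "BR", "K"))
      return(toupper(nm))
    toupper(first)
  }, character(1), USE.NAMES = FALSE)
}

# Convert a length to Angstrom given a declared unit.
#' Convert a length value to Angstrom
#' @param x numeric value(s)
#' @param unit "angstrom" (default) or "nm"
#' @export
as_angstrom <- function(x, unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  if (unit == "nm") x * 10 else x
}
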