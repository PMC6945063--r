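# Parameter assignment: maps (res_name, atom name) to partial charge (e),
# radius (Angstrom) and Lennard-Jones (eps kJ/mol, sigma Angstrom).

#' Load a (residue, atom) -> (charge, radius, eps, sigma) parameter table
#'
#' With no argument, loads the parameter set bundled with the package: a
#' minimal self-contained fixed-point-charge set covering the 20 standard
#' amino acids (heavy atoms, hydrogen charges folded in), phosphoserine
#' (SEP, net -2 e) and monatomic ions. Residue charge sums are integral by
#' construction.
#'
#' @param path TSV with columns `res_name`, `atom`, `charge`, `radius`,
#'   `eps`, `sigma`; `#` comment lines are skipped.
#' @return data.frame parameter table
#' @export
load_parameter_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ff_params.tsv", package = "phosbind")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  req <- c("res_name", "atom", "charge", "radius", "eps", "sigma")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(tab$res_name, tab$atom)))
    stop("duplicate (res_name, atom) entries in parameter table")
  tab
}

#' Assign charges, radii and LJ parameters to every atom
#'
#' Every atom must be found in the table; unknown (residue, atom) pairs
#' raise one error listing all misses so nothing is silently zeroed.
#' Idempotent: reassigning with the same table is a no-op.
#'
#' @param s param_structure
#' @param table parameter table from [load_parameter_table()] (default:
#'   bundled set)
#' @return param_structure with parameters populated
#' @export
assign_parameters <- function(s, table = load_parameter_table()) {
  a <- s$atoms
  key <- paste(a$res_name, a$name)
  idx <- match(key, paste(table$res_name, table$atom))
  if (anyNA(idx)) {
    misses <- unique(key[is.na(idx)])
    stop("no parameters for ", length(misses), " (residue, atom) pair(s): ",
         paste(misses, collapse = ", "))
  }
  a$charge <- table$charge[idx]
  a$radius <- table$radius[idx]
  a$eps <- table$eps[idx]
  a$sigma <- table$sigma[idx]
  out <- s
  out$atoms <- a
  chk <- total_charge(out)
  if (abs(chk - round(chk)) > 1e-6)
    warning("total charge ", format(chk), " e is not integral; ",
            "structure may be missing atoms relative to the parameter set")
  out
}

#' Total charge of a structure (e)
#' @param s param_structure
#' @export
total_charge <- function(s) sum(s$atoms$charge)

#' Per-residue charge sums
#' @param s param_structure
#' @return data.frame with chain_id, res_seq, res_name, charge
#' @export
residue_charges <- function(s) {
  a <- s$atoms
  agg <- stats::aggregate(charge ~ chain_id + res_seq + res_name, data = a,
                          FUN = sum)
  agg[order(agg$chain_id, agg$res_seq), ]
}

#' Remove hydrogen atoms
#'
#' The bundled parameter set is heavy-atom only (hydrogen charges folded
#' in); structures carrying explicit hydrogens are stripped before
#' assignment.
#'
#' @param s param_structure
#' @export
strip_hydrogens <- function(s) {
  keep <- which(s$atoms$is_heavy)
  if (length(keep) == 0) stop("structure has no heavy atoms")
  subset_structure(s, keep)
}
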