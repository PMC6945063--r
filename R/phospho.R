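# Phosphoserine building: converts SER -> SEP by grafting a tetrahedral
# phosphate onto OG, scanning the CB-OG torsion for the least-clashing
# rotamer, and reassigning charges so the residue carries -2 e (fully
# deprotonated phosphate, the physiological-pH convention).

P_OG_BOND <- 1.61     # P-OG bond length, Angstrom
P_O_BOND <- 1.48      # P-O(terminal) bond length, Angstrom
CB_OG_P_ANGLE <- 119  # degrees
TETRAHEDRAL <- 109.47 # degrees

# Place atom D given positions A, B, C so that |C-D| = bond,
# angle(B,C,D) = angle (deg) and dihedral(A,B,C,D) = torsion (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- pracma_cross(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build a phosphoserine onto a serine residue
#'
#' Renames the residue SER -> SEP, removes the hydroxyl hydrogen if
#' present, and adds P, O1P, O2P, O3P: P at 1.61 Angstrom from OG with a
#' tetrahedral oxygen cap (P-O 1.48 Angstrom), the phosphate torsion about
#' CB-OG scanned at 10 degree steps and the rotamer maximizing the minimum
#' non-bonded heavy-atom distance retained. Parameters of the modified
#' residue are reassigned from `table` so its net charge is -2 e. All atoms
#' outside the target residue are untouched.
#'
#' @param s param_structure
#' @param chain chain identifier of the target residue
#' @param res residue number of the target residue
#' @param table parameter table used to recharge the new SEP residue
#' @return param_structure with the phosphoserine built
#' @export
build_phosphoserine <- function(s, chain, res, table = load_parameter_table()) {
  a <- s$atoms
  in_res <- a$chain_id == chain & a$res_seq == res
  if (!any(in_res)) stop("residue ", chain, ":", res, " not found")
  rname <- unique(a$res_name[in_res])
  if (identical(rname, "SEP"))
    stop("residue ", chain, ":", res, " is already SEP")
  if (!identical(rname, "SER"))
    stop("residue ", chain, ":", res, " is ", rname, ", not SER")
  need <- c("CA", "CB", "OG")
  have <- a$name[in_res]
  if (!all(need %in% have))
    stop("residue ", chain, ":", res, " is missing atoms: ",
         paste(setdiff(need, have), collapse = ", "))

  # drop hydroxyl hydrogen
  drop <- in_res & a$name %in% c("HG", "HG1")
  if (any(drop)) a <- a[!drop, , drop = FALSE]
  in_res <- a$chain_id == chain & a$res_seq == res

  pos <- function(nm) unlist(a[in_res & a$name == nm, c("x", "y", "z")],
                             use.names = FALSE)
  ca <- pos("CA"); cb <- pos("CB"); og <- pos("OG")

  other_heavy <- a$is_heavy & !(in_res & a$name %in% c("OG", "CB"))
  other_xyz <- as.matrix(a[other_heavy, c("x", "y", "z")])

  build_rotamer <- function(t) {
    p <- place_atom(ca, cb, og, P_OG_BOND, CB_OG_P_ANGLE, t)
    os <- lapply(c(60, 180, 300), function(tt)
      place_atom(cb, og, p, P_O_BOND, TETRAHEDRAL, tt))
    rbind(p, os[[1]], os[[2]], os[[3]])
  }
  score_rotamer <- function(xyz_new) {
    if (nrow(other_xyz) == 0) return(Inf)
    min(vapply(seq_len(nrow(xyz_new)), function(i)
      min(sqrt(rowSums((other_xyz -
        matrix(xyz_new[i, ], nrow(other_xyz), 3, byrow = TRUE))^2))),
      numeric(1)))
  }
  torsions <- seq(0, 350, by = 10)
  scores <- vapply(torsions, function(t) score_rotamer(build_rotamer(t)),
                   numeric(1))
  best <- build_rotamer(torsions[which.max(scores)])

  a$res_name[in_res] <- "SEP"
  max_serial <- max(a$serial)
  new_rows <- data.frame(
    serial = max_serial + 1:4,
    name = c("P", "O1P", "O2P", "O3P"),
    elem = c("P", "O", "O", "O"),
    res_name = "SEP", res_seq = res, chain_id = chain,
    x = best[, 1], y = best[, 2], z = best[, 3],
    charge = 0, radius = 0, eps = 0, sigma = 0,
    is_heavy = TRUE, is_sidechain = TRUE,
    stringsAsFactors = FALSE)
  og_row <- which(in_res & a$name == "OG")
  a <- rbind(a[seq_len(og_row), , drop = FALSE], new_rows,
             if (og_row < nrow(a)) a[(og_row + 1):nrow(a), , drop = FALSE])
  out <- param_structure(a, title = s$title)

  # recharge only the modified residue
  in_res <- out$atoms$chain_id == chain & out$atoms$res_seq == res
  key <- paste(out$atoms$res_name[in_res], out$atoms$name[in_res])
  idx <- match(key, paste(table$res_name, table$atom))
  if (anyNA(idx))
    stop("no SEP parameters for atom(s): ",
         paste(key[is.na(idx)], collapse = ", "),
         " (strip hydrogens before building)")
  out$atoms$charge[in_res] <- table$charge[idx]
  out$atoms$radius[in_res] <- table$radius[idx]
  out$atoms$eps[in_res] <- table$eps[idx]
  out$atoms$sigma[in_res] <- table$sigma[idx]
  out
}
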