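# Structure and trajectory I/O. Parsing of the fixed-column PDB and
# whitespace-delimited PQR formats is delegated to bio3d; this layer adds
# validation (line-level error reporting, frame congruence) and converts to
# the package's containers.

bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | !nzchar(trimws(ifelse(is.na(elem), "", elem)))
  if (any(bad)) elem[bad] <- element_from_name(a$elety[bad])
  data.frame(serial = a$eleno, name = trimws(a$elety),
             elem = trimws(elem), res_name = trimws(a$resid),
             res_seq = a$resno,
             chain_id = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
             x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

# Locate ATOM/HETATM lines whose fixed-column coordinate fields fail to
# parse, so errors can name the offending line.
check_pdb_coord_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop("malformed coordinate field in '", basename(path), "' line ", i,
           ": ", trimws(lines[i]), call. = FALSE)
  }
  invisible(sum(rec))
}

#' Read a PDB file into a param_structure
#'
#' Charges, radii and LJ parameters are zero-filled until
#' [assign_parameters()] is called. Multi-MODEL files return the first model
#' with a warning; use [read_trajectory()] to keep all models.
#'
#' @param path PDB file path
#' @return param_structure
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_rec <- check_pdb_coord_lines(path)
  if (n_rec == 0) stop("no ATOM/HETATM records in ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  n_models <- nrow(pdb$xyz)
  if (!is.null(n_models) && n_models > 1)
    warning("'", basename(path), "' contains ", n_models,
            " MODELs; returning the first (use read_trajectory for all)")
  param_structure(bio3d_to_atoms(pdb), title = basename(path))
}

#' Read a PQR file (whitespace-delimited) into a param_structure
#'
#' Populates per-atom charge (e) and radius (Angstrom) from the last two
#' columns of each record. PQR is free-format: records are tokenized on
#' whitespace (the chain field is optional), so both column-aligned and
#' minimally spaced files are accepted.
#'
#' @param path PQR file path
#' @return param_structure
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  if (length(rec) == 0) stop("no ATOM/HETATM records in ", path)
  rows <- lapply(rec, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    # with chain: rec serial name res chain resseq x y z q r  (11 tokens)
    # without:    rec serial name res resseq x y z q r        (10 tokens)
    if (length(tok) == 11) {
      chain <- tok[5]; rest <- tok[6:11]
    } else if (length(tok) == 10) {
      chain <- "A"; rest <- tok[5:10]
    } else stop("malformed PQR record in '", basename(path), "' line ", i,
                ": expected 10 or 11 fields, got ", length(tok),
                call. = FALSE)
    num <- suppressWarnings(as.numeric(c(tok[2], rest)))
    if (anyNA(num))
      stop("non-numeric field in '", basename(path), "' line ", i,
           call. = FALSE)
    data.frame(serial = as.integer(num[1]), name = tok[3],
               elem = element_from_name(tok[3]), res_name = tok[4],
               res_seq = as.integer(num[2]), chain_id = chain,
               x = num[3], y = num[4], z = num[5],
               charge = num[6], radius = num[7], stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  if (any(atoms$radius < 0)) stop("negative radius in ", path)
  param_structure(atoms, title = basename(path))
}

#' Write a param_structure to PQR
#' @param s param_structure with charges and radii assigned
#' @param path output path
#' @return invisibly, the path
#' @export
write_pqr <- function(s, path) {
  a <- s$atoms
  bio3d::write.pqr(file = path,
                   eleno = a$serial, elety = a$name, resid = a$res_name,
                   chain = a$chain_id, resno = a$res_seq,
                   xyz = as.numeric(t(coords(s))),
                   o = a$charge, b = a$radius)
  invisible(path)
}

#' Write a param_structure to PDB
#' @param s param_structure
#' @param path output path
#' @param b optional per-atom B-factor vector
#' @return invisibly, the path
#' @export
write_pdb <- function(s, path, b = NULL) {
  a <- s$atoms
  if (is.null(b)) b <- rep(0, nrow(a))
  bio3d::write.pdb(file = path,
                   eleno = a$serial, elety = a$name, resid = a$res_name,
                   chain = a$chain_id, resno = a$res_seq,
                   xyz = as.numeric(t(coords(s))),
                   o = rep(1, nrow(a)), b = b, elesy = a$elem)
  invisible(path)
}

#' Map per-residue values onto the B-factor column of a written PDB
#'
#' Used to visualize residue-wise binding energy decompositions: every atom
#' of a residue receives that residue's value, clamped to the PDB B-factor
#' field range \[-99.99, 999.99\] (clamping emits a warning).
#'
#' @param s param_structure
#' @param per_residue_values named numeric vector; names are "chain:res_seq"
#'   keys (e.g. `"A:93"`)
#' @param path output PDB path
#' @return invisibly, the path
#' @export
write_bfactor_map <- function(s, per_residue_values, path) {
  if (any(!is.finite(per_residue_values))) stop("non-finite residue values")
  keys <- paste0(s$atoms$chain_id, ":", s$atoms$res_seq)
  missing_keys <- setdiff(names(per_residue_values), unique(keys))
  if (length(missing_keys) > 0)
    stop("residue keys absent from structure: ",
         paste(missing_keys, collapse = ", "))
  b <- rep(0, n_atoms(s))
  hit <- keys %in% names(per_residue_values)
  b[hit] <- per_residue_values[keys[hit]]
  clamped <- b < -99.99 | b > 999.99
  if (any(clamped)) {
    warning(sum(clamped), " atom B-factor value(s) clamped to [-99.99, 999.99]")
    b <- pmin(pmax(b, -99.99), 999.99)
  }
  write_pdb(s, path, b = b)
}

# Count atoms per MODEL block to name the offending frame on mismatch.
pdb_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(model_starts) == 0) return(sum(is_atom))
  ends <- c(model_starts[-1] - 1, length(lines))
  vapply(seq_along(model_starts), function(i)
    sum(is_atom[model_starts[i]:ends[i]]), integer(1))
}

#' Read a trajectory from a multi-model PDB or a coordinate TSV
#'
#' The TSV format has columns `frame`, `serial`, `x`, `y`, `z` (Angstrom)
#' and optionally `time_ps`. Times absent from the file are synthesized
#' from `timestep_ps`.
#'
#' @param path file path (format detected from extension: `.pdb` vs
#'   `.tsv`/`.txt`)
#' @param topology param_structure the frames must be congruent with
#' @param timestep_ps time spacing used when the file carries no times
#' @return trajectory
#' @export
read_trajectory <- function(path, topology, timestep_ps = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  na <- n_atoms(topology)
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    counts <- pdb_model_atom_counts(path)
    bad <- which(counts != na)
    if (length(bad) > 0)
      stop("frame ", bad[1], " has ", counts[bad[1]],
           " atoms; topology has ", na)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
    xyz <- pdb$xyz
    if (is.null(nrow(xyz))) xyz <- matrix(xyz, nrow = 1)
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    trajectory(topology, frames, timestep_ps = timestep_ps)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    req <- c("frame", "serial", "x", "y", "z")
    miss <- setdiff(req, names(tab))
    if (length(miss) > 0)
      stop("coordinate table missing columns: ", paste(miss, collapse = ", "))
    frames_idx <- sort(unique(tab$frame))
    serial_order <- topology$atoms$serial
    frames <- vector("list", length(frames_idx))
    times <- numeric(length(frames_idx))
    for (k in seq_along(frames_idx)) {
      sub <- tab[tab$frame == frames_idx[k], , drop = FALSE]
      if (nrow(sub) != na)
        stop("frame ", frames_idx[k], " has ", nrow(sub),
             " atoms; topology has ", na)
      sub <- sub[match(serial_order, sub$serial), , drop = FALSE]
      if (anyNA(sub$serial))
        stop("frame ", frames_idx[k], " serials do not match topology")
      frames[[k]] <- as.matrix(sub[, c("x", "y", "z")])
      times[k] <- if ("time_ps" %in% names(sub)) sub$time_ps[1]
                  else (k - 1) * timestep_ps
    }
    trajectory(topology, frames, times = times)
  }
}

#' Write a trajectory as a coordinate TSV
#'
#' Coordinates are written with 17 significant digits so that a read/write
#' round trip is bitwise exact.
#'
#' @param traj trajectory
#' @param path output path
#' @return invisibly, the path
#' @export
write_trajectory <- function(traj, path) {
  na <- n_atoms(traj$topology)
  serials <- traj$topology$atoms$serial
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame\tserial\tx\ty\tz\ttime_ps", con)
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    writeLines(sprintf("%d\t%d\t%.17g\t%.17g\t%.17g\t%.17g",
                       k, serials, f[, 1], f[, 2], f[, 3], traj$times[k]), con)
  }
  invisible(path)
}
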