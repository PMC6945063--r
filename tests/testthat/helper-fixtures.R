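# Fixtures built in code; no data files.

# Minimal structure from explicit atom specs.
make_atoms <- function(names, res_names, res_seqs, chains, xyz,
                       charge = 0, radius = 0, eps = 0, sigma = 0,
                       elem = NULL) {
  if (is.null(elem)) elem <- substr(names, 1, 1)
  param_structure(data.frame(
    serial = seq_along(names), name = names, elem = elem,
    res_name = res_names, res_seq = res_seqs, chain_id = chains,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge, radius = radius, eps = eps, sigma = sigma,
    stringsAsFactors = FALSE))
}

# Two free atoms with explicit LJ/charge parameters at separation r.
two_atom_system <- function(r, q = c(0, 0), eps = c(1, 1), sigma = c(3, 3),
                            radius = c(1.7, 1.7)) {
  make_atoms(c("C1", "C2"), "TOY", c(1L, 2L), c("A", "B"),
             rbind(c(0, 0, 0), c(r, 0, 0)),
             charge = q, radius = radius, eps = eps, sigma = sigma,
             elem = c("C", "C"))
}

# A central atom fully enclosed by a shell of blocker atoms.
shell_fixture <- function(r_center = 1.9, shell_dist = 4.5,
                          r_shell = 2.0, n_shell = 60) {
  golden <- pi * (3 - sqrt(5))
  t <- seq_len(n_shell) - 0.5
  z <- 1 - 2 * t / n_shell
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (t - 0.5)
  xyz <- rbind(c(0, 0, 0),
               cbind(shell_dist * rho * cos(th), shell_dist * rho * sin(th),
                     shell_dist * z))
  make_atoms(paste0("C", seq_len(n_shell + 1)), "TOY",
             seq_len(n_shell + 1), "A", xyz,
             radius = c(r_center, rep(r_shell, n_shell)),
             elem = rep("C", n_shell + 1))
}

# Independent brute-force event enumeration: explicit frame-by-frame walk,
# no rle. Mirrors the documented rule (<= cutoff is contact, event must be
# entered by a crossing, runs from frame 1 flagged as initial contact).
brute_force_events <- function(d, cutoff, dwell_min) {
  n <- length(d)
  events <- list()
  i <- 1
  while (i <= n) {
    if (d[i] <= cutoff) {
      j <- i
      while (j < n && d[j + 1] <= cutoff) j <- j + 1
      if (j - i + 1 >= dwell_min)
        events[[length(events) + 1]] <-
          data.frame(start_frame = i, end_frame = j, dwell = j - i + 1,
                     initial_contact = (i == 1))
      i <- j + 1
    } else i <- i + 1
  }
  if (length(events) == 0)
    return(data.frame(start_frame = integer(0), end_frame = integer(0),
                      dwell = integer(0), initial_contact = logical(0)))
  do.call(rbind, events)
}

# Write a tiny hand-rolled PDB text fixture.
write_toy_pdb <- function(path, lines) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, res, chain, resno, x, y, z) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, res, chain, resno, x, y, z)
}
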