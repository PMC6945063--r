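# Synthetic fixtures with known ground truth: Born ions and toy two-chain
# charge systems for the energetics, telegraph contact trajectories for
# event detection, alignments with controlled per-column conservation, and
# substrate windows drawn from a known motif. All generators are
# deterministic given (spec, seed); a single global seed fans out to
# per-generator streams by stable hashing of the generator name.

#' Derive a per-generator stream seed from a global seed
#' @param seed global integer seed
#' @param name generator name
#' @return integer seed below 2^31
#' @export
stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((as.numeric(seed) * 104729 + h) %% 2147483647)
}

#' Evaluate code with a temporary RNG seed, restoring the RNG state
#' @param seed integer seed
#' @param code expression
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Born ion fixture: a single charged sphere
#'
#' The closed-form solvation energy
#' -(f/2) (q^2/R) (1/eps_in - 1/eps_out) is attached as the
#' `born_energy` attribute (function of the two dielectrics) for test
#' harnesses; see also [born_energy()].
#'
#' @param q charge, e
#' @param R radius, Angstrom
#' @return param_structure with one atom at the origin
#' @export
gen_born_system <- function(q = 1.0, R = 2.0) {
  if (R <= 0) stop("Born radius must be > 0")
  s <- param_structure(data.frame(
    serial = 1L, name = "Q", elem = "Q", res_name = "ION", res_seq = 1L,
    chain_id = "A", x = 0, y = 0, z = 0, charge = q, radius = R,
    eps = 0, sigma = 0, stringsAsFactors = FALSE), title = "Born ion")
  attr(s, "born_energy") <- function(eps_in = 2, eps_out = 80)
    born_energy(q, R, eps_in, eps_out)
  s
}

#' Closed-form Born solvation energy (kJ/mol)
#' @param q charge, e
#' @param R radius, Angstrom
#' @param eps_in,eps_out dielectric constants
#' @export
born_energy <- function(q, R, eps_in = 2, eps_out = 80) {
  -(COULOMB_CONST / 2) * (q^2 / R) * (1 / eps_in - 1 / eps_out)
}

#' Specification for a toy two-chain complex
#' @param atoms_per_chain atoms in each chain
#' @param charges_A,charges_B per-atom charges, e (recycled)
#' @param separation chain center distance, Angstrom
#' @param seed integer
#' @export
toy_complex_spec <- function(atoms_per_chain = 1, charges_A = 1,
                             charges_B = -1, separation = 10, seed = 1) {
  stopifnot(atoms_per_chain >= 1, separation > 0)
  list(atoms_per_chain = atoms_per_chain,
       charges_A = rep_len(charges_A, atoms_per_chain),
       charges_B = rep_len(charges_B, atoms_per_chain),
       separation = separation, seed = seed)
}

#' Generate a toy two-chain charge complex with a closed-form reference
#'
#' Chain centers sit `separation` Angstrom apart along x; atoms beyond the
#' first per chain are scattered near the center with a minimum spacing.
#' The reference vacuum interaction energy (attribute `reference_energy`)
#' is computed by an explicit double loop over inter-chain pairs
#' (Coulomb + Lennard-Jones), independent of the package's energy code.
#'
#' @param spec [toy_complex_spec()]
#' @return param_structure with chains A and B, generic carbon-like LJ
#'   parameters, and attributes `reference_energy`, `reference_coulomb`,
#'   `reference_lj` (kJ/mol)
#' @export
gen_toy_complex <- function(spec = toy_complex_spec()) {
  n <- spec$atoms_per_chain
  gen_chain <- function(center) {
    if (n == 1) return(matrix(center, 1, 3, byrow = TRUE))
    for (attempt in 1:100) {
      xyz <- matrix(stats::runif(3 * (n - 1), -2.5, 2.5), ncol = 3)
      xyz <- rbind(c(0, 0, 0), xyz)
      if (min(stats::dist(xyz)) > 2.5)
        return(sweep(xyz, 2, center, "+"))
    }
    stop("could not place chain atoms without overlap after 100 attempts")
  }
  s <- with_seed(spec$seed, {
    xa <- gen_chain(c(0, 0, 0))
    xb <- gen_chain(c(spec$separation, 0, 0))
    xyz <- rbind(xa, xb)
    if (min(stats::dist(xyz)) <= 2)
      stop("inter-chain overlap; increase separation")
    param_structure(data.frame(
      serial = seq_len(2 * n), name = "C", elem = "C", res_name = "TOY",
      res_seq = rep(seq_len(n), 2),
      chain_id = rep(c("A", "B"), each = n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = c(spec$charges_A, spec$charges_B),
      radius = 1.7, eps = 0.3, sigma = 3.4,
      stringsAsFactors = FALSE), title = "toy complex")
  })
  # independent brute-force reference over inter-chain pairs
  a <- s$atoms
  ia <- which(a$chain_id == "A"); ib <- which(a$chain_id == "B")
  e_c <- 0; e_lj <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    e_c <- e_c + COULOMB_CONST * a$charge[i] * a$charge[j] / r
    sij <- (a$sigma[i] + a$sigma[j]) / 2
    eij <- sqrt(a$eps[i] * a$eps[j])
    e_lj <- e_lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  attr(s, "reference_coulomb") <- e_c
  attr(s, "reference_lj") <- e_lj
  attr(s, "reference_energy") <- e_c + e_lj
  s
}

#' Specification for a telegraph (two-state) contact trajectory
#' @param k_on,k_off per-frame switch probabilities, in (0,1)
#' @param mean_bound,mean_unbound state mean distances, Angstrom
#' @param noise_sd Gaussian distance noise, Angstrom
#' @param n_frames frame count
#' @param seed integer
#' @export
telegraph_spec <- function(k_on = 0.005, k_off = 0.002, mean_bound = 4.5,
                           mean_unbound = 9.0, noise_sd = 0.3,
                           n_frames = 5000, seed = 1) {
  stopifnot(k_on > 0 || k_off > 0, k_on <= 1, k_off <= 1, k_on >= 0,
            mean_bound > 0, mean_unbound > mean_bound, noise_sd >= 0,
            n_frames >= 1)
  list(k_on = k_on, k_off = k_off, mean_bound = mean_bound,
       mean_unbound = mean_unbound, noise_sd = noise_sd,
       n_frames = n_frames, seed = seed)
}

#' Generate a two-state (bound/unbound) contact trajectory
#'
#' A two-residue topology whose inter-residue side-chain distance follows a
#' telegraph process with Gaussian noise. The chain starts unbound. Ground
#' truth is recorded: per-frame states and the frames of unbound-to-bound
#' switches (the true formation events).
#'
#' @param spec [telegraph_spec()]
#' @param timestep_ps frame spacing
#' @return list: `traj` (trajectory), `series` (contact_series),
#'   `states` (logical, TRUE = bound), `true_events` (data.frame
#'   start_frame/end_frame of bound intervals entered by a switch),
#'   `spec`
#' @export
gen_contact_trajectory <- function(spec = telegraph_spec(), timestep_ps = 1) {
  out <- with_seed(spec$seed, {
    n <- spec$n_frames
    bound <- logical(n)
    state <- FALSE
    u <- stats::runif(n)
    for (t in seq_len(n)) {
      p_switch <- if (state) spec$k_off else spec$k_on
      if (u[t] < p_switch) state <- !state
      bound[t] <- state
    }
    d <- ifelse(bound, spec$mean_bound, spec$mean_unbound) +
      stats::rnorm(n, 0, spec$noise_sd)
    d <- pmax(d, 0.5)
    list(bound = bound, d = d)
  })
  bound <- out$bound; d <- out$d

  r <- rle(bound)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & starts > 1   # bound runs entered by a switch
  true_events <- data.frame(start_frame = starts[keep],
                            end_frame = ends[keep])

  topo <- param_structure(data.frame(
    serial = 1:4, name = c("CA", "CB", "CA", "CB"), elem = "C",
    res_name = "TOY", res_seq = c(1L, 1L, 2L, 2L), chain_id = "A",
    x = c(0, 1.5, 3, 4.5), y = 0, z = 0,
    stringsAsFactors = FALSE), title = "telegraph pair")
  frames <- lapply(d, function(dd)
    matrix(c(0, 0, 0, 1.5, 0, 0, 1.5 + dd + 1.5, 0, 0, 1.5 + dd, 0, 0),
           ncol = 3, byrow = TRUE))
  traj <- trajectory(topo, frames, timestep_ps = timestep_ps)
  list(traj = traj,
       series = contact_series(d, times = traj$times),
       states = bound, true_events = true_events, spec = spec)
}

#' Specification for a synthetic ortholog alignment
#' @param n_sequences rows
#' @param n_columns columns
#' @param p per-column conservation probabilities in \[0.05, 1\] (recycled)
#' @param seed integer
#' @export
alignment_spec <- function(n_sequences = 207, n_columns = 60,
                           p = seq(0.1, 1, by = 0.1), seed = 1) {
  p <- rep_len(p, n_columns)
  if (any(p < 0.05 | p > 1)) stop("conservation p must be in [0.05, 1]")
  stopifnot(n_sequences >= 2)
  list(n_sequences = n_sequences, n_columns = n_columns, p = p, seed = seed)
}

#' Generate an alignment with controlled per-column conservation
#'
#' Column c carries its consensus residue with probability p\[c\], else a
#' residue uniform over the remaining 19. Consensus residues cycle through
#' the amino-acid alphabet. The generating p vector is attached as
#' attribute `p`; consensus residues as attribute `consensus`.
#'
#' @param spec [alignment_spec()]
#' @return alignment
#' @export
gen_alignment <- function(spec = alignment_spec()) {
  cons <- AMINO_ACIDS[(seq_len(spec$n_columns) - 1) %% 20 + 1]
  m <- with_seed(spec$seed, {
    m <- matrix("", spec$n_sequences, spec$n_columns)
    for (j in seq_len(spec$n_columns)) {
      hit <- stats::runif(spec$n_sequences) < spec$p[j]
      other <- sample(setdiff(AMINO_ACIDS, cons[j]), spec$n_sequences,
                      replace = TRUE)
      m[, j] <- ifelse(hit, cons[j], other)
    }
    m
  })
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- paste0("ortholog", seq_along(seqs))
  aln <- alignment(seqs)
  attr(aln, "p") <- spec$p
  attr(aln, "consensus") <- cons
  aln
}

#' A TBK1-substrate-like position probability matrix (synthetic)
#'
#' A sparse, position-specific 15 x 20 PPM emulating the shape of a kinase
#' substrate motif estimated from a small substrate set: serine fixed at
#' the center (position 8), a strong hydrophobic (leucine) preference
#' immediately after the phosphosite, acidic preferences upstream, and at
#' every other position probability concentrated on a few residues (0.60 /
#' 0.20 / 0.15 with a 0.05 tail spread over the remaining seventeen), as
#' empirical motifs from tens of substrates are. Purely synthetic; used as
#' generating truth for motif-recovery fixtures.
#'
#' @return 20 x 15 probability matrix (rows = residues)
#' @export
tbk1_like_ppm <- function() {
  ppm <- matrix(0, nrow = 20, ncol = MOTIF_WIDTH,
                dimnames = list(AMINO_ACIDS, NULL))
  prefer <- function(pos, residues, w = c(0.60, 0.20, 0.15)) {
    p <- rep(0.05 / (20 - length(residues)), 20)
    p[match(residues, AMINO_ACIDS)] <- w
    ppm[, pos] <<- p / sum(p)
  }
  # positions 1..7: N-terminal flank with acidic/polar preferences
  prefer(1, c("L", "S", "E"))
  prefer(2, c("S", "T", "A"))
  prefer(3, c("D", "E", "S"))
  prefer(4, c("A", "G", "P"))
  prefer(5, c("D", "E", "N"))
  prefer(6, c("E", "D", "Q"))
  prefer(7, c("G", "S", "A"))
  ppm[, 8] <- 0; ppm["S", 8] <- 1    # central phosphoserine
  # positions 9..15: hydrophobic +1 and C-terminal flank
  prefer(9, c("L", "I", "M"))
  prefer(10, c("L", "V", "F"))
  prefer(11, c("S", "T", "G"))
  prefer(12, c("E", "D", "K"))
  prefer(13, c("L", "A", "S"))
  prefer(14, c("S", "P", "E"))
  prefer(15, c("L", "E", "A"))
  ppm
}

#' Draw substrate 15-mer windows from a known PPM
#'
#' @param ppm 20 x 15 probability matrix (rows named by residue)
#' @param n number of windows
#' @param seed integer
#' @param force_center_s force position 8 to serine (phosphosite
#'   convention) regardless of the PPM
#' @return character vector of 15-mers
#' @export
gen_substrate_windows <- function(ppm = tbk1_like_ppm(), n = 1000, seed = 1,
                                  force_center_s = FALSE) {
  stopifnot(nrow(ppm) == 20, ncol(ppm) == MOTIF_WIDTH)
  if (max(abs(colSums(ppm) - 1)) > 1e-8)
    stop("PPM columns must sum to 1")
  with_seed(seed, {
    m <- vapply(seq_len(MOTIF_WIDTH), function(p)
      sample(rownames(ppm), n, replace = TRUE, prob = ppm[, p]),
      character(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    if (force_center_s) m[, MOTIF_CENTER] <- "S"
    apply(m, 1, paste, collapse = "")
  })
}

#' Build an idealized extended tripeptide fixture
#'
#' Constructs backbone and minimal side-chain heavy atoms (CB, plus OG for
#' serine) with standard bond lengths and extended (phi = psi = 180)
#' torsions. Used as the substrate of the phosphoserine-builder and
#' accessibility fixtures; parameters are assigned from the bundled table.
#'
#' @param residues 3-letter codes, default Ala-Ser-Ala
#' @param chain chain identifier
#' @param parameterize assign bundled charges/radii (default TRUE)
#' @return param_structure
#' @export
gen_tripeptide <- function(residues = c("ALA", "SER", "ALA"), chain = "A",
                           parameterize = TRUE) {
  rows <- list()
  serial <- 0L
  add <- function(name, elem, res_name, res_seq, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, elem = elem, res_name = res_name,
      res_seq = res_seq, chain_id = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  }
  # first residue backbone seeded explicitly
  n_pos <- c(0, 0, 0)
  ca_pos <- c(1.46, 0, 0)
  c_pos <- place_atom(c(0, 1, 0), n_pos, ca_pos, 1.52, 111, 180)
  for (i in seq_along(residues)) {
    rn <- residues[i]
    add("N", "N", rn, i, n_pos)
    add("CA", "C", rn, i, ca_pos)
    add("C", "C", rn, i, c_pos)
    if (rn != "GLY") {
      cb <- place_atom(c_pos, n_pos, ca_pos, 1.53, 110.5, -120)
      add("CB", "C", rn, i, cb)
      if (rn %in% c("SER", "SEP")) {
        og <- place_atom(n_pos, ca_pos, cb, 1.41, 110.5, 180)
        add("OG", "O", rn, i, og)
      }
    }
    if (i < length(residues)) {
      n_next <- place_atom(n_pos, ca_pos, c_pos, 1.33, 114, 180)
      add("O", "O", rn, i, place_atom(n_pos, ca_pos, c_pos, 1.23, 121, 0))
      ca_next <- place_atom(ca_pos, c_pos, n_next, 1.46, 123, 180)
      c_next <- place_atom(c_pos, n_next, ca_next, 1.52, 111, 180)
      n_pos <- n_next; ca_pos <- ca_next; c_pos <- c_next
    } else {
      add("O", "O", rn, i, place_atom(n_pos, ca_pos, c_pos, 1.23, 121, 0))
    }
  }
  s <- param_structure(do.call(rbind, rows), title = "tripeptide fixture")
  if (parameterize) s <- assign_parameters(s)
  s
}
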