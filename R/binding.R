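# MM-PBSA binding free energy over trajectory frames (single-trajectory
# scheme: receptor and ligand conformations are taken from the complex
# frames, so bonded terms cancel identically). The configurational-entropy
# term -T dS is not evaluated and is reported as documented-absent; totals
# are dE_vdW + dE_elec + ddG_polar + ddG_nonpolar.

frame_structure <- function(traj, k) set_coords(traj$topology, traj$frames[[k]])

#' MM-PBSA binding free energy of a two-chain complex over a trajectory
#'
#' Per (subsampled) frame: inter-chain Lennard-Jones and vacuum Coulomb
#' terms (all pairs, no cutoff), the polar solvation difference from
#' [polar_binding()], and the nonpolar difference
#' gamma * (SASA_AB - SASA_A - SASA_B) (the SASA model offsets cancel in
#' the difference).
#'
#' @param traj trajectory whose topology has parameters assigned
#' @param chainA,chainB chain identifiers partitioning the structure
#' @param pb [pb_config()]
#' @param sasa_cfg [sasa_config()]
#' @param frame_interval_ps evaluation interval; frames are subsampled so
#'   consecutive evaluated frames are at least this far apart (default 0:
#'   every frame)
#' @param keep_per_atom keep per-frame per-atom polar/nonpolar splits (for
#'   [residue_decomposition()])
#' @return object of class `energy_breakdown`
#' @export
binding_energy <- function(traj, chainA, chainB, pb = pb_config(),
                           sasa_cfg = sasa_config(), frame_interval_ps = 0,
                           keep_per_atom = FALSE) {
  s0 <- traj$topology
  ia <- atom_select(s0, chain = chainA)
  ib <- atom_select(s0, chain = chainB)
  if (length(ia) + length(ib) != n_atoms(s0))
    stop("chains ", chainA, " and ", chainB, " do not partition the structure")

  sel <- subsample_frames(traj$times, frame_interval_ps)
  if (length(sel) < 1) stop("no frames left after subsampling")

  per_frame <- lapply(sel, function(k) {
    s <- frame_structure(traj, k)
    elec_mat <- coulomb_pair_matrix(s, ia, ib, eps = 1)
    vdw_mat <- lj_pair_matrix(s, ia, ib)
    pol <- polar_binding(s, chainA, chainB, pb)
    sas_ab <- sasa(s, sasa_cfg)$per_atom
    sas_a <- sas_b <- numeric(n_atoms(s))
    sas_a[ia] <- sasa(subset_structure(s, ia), sasa_cfg)$per_atom
    sas_b[ib] <- sasa(subset_structure(s, ib), sasa_cfg)$per_atom
    np_per_atom <- sasa_cfg$gamma * (sas_ab - sas_a - sas_b)
    out <- list(e_vdw = sum(vdw_mat), e_elec = sum(elec_mat),
                g_polar = pol$ddg, g_nonpolar = sum(np_per_atom))
    if (keep_per_atom) {
      mm_split <- function(m) {
        v <- numeric(n_atoms(s))
        v[ia] <- 0.5 * rowSums(m)
        v[ib] <- v[ib] + 0.5 * colSums(m)
        v
      }
      out$per_atom <- cbind(vdw = mm_split(vdw_mat), elec = mm_split(elec_mat),
                            polar = pol$per_atom, nonpolar = np_per_atom)
    }
    out
  })

  comp <- function(nm) vapply(per_frame, `[[`, numeric(1), nm)
  terms <- list(e_vdw = comp("e_vdw"), e_elec = comp("e_elec"),
                g_polar = comp("g_polar"), g_nonpolar = comp("g_nonpolar"))
  terms$total <- terms$e_vdw + terms$e_elec + terms$g_polar + terms$g_nonpolar
  structure(list(
    terms = terms,
    frames = sel, times = traj$times[sel],
    chainA = chainA, chainB = chainB,
    entropy_term = NA_real_,   # -T dS: not evaluated, never part of totals
    per_atom = if (keep_per_atom) lapply(per_frame, `[[`, "per_atom"),
    topology = s0
  ), class = "energy_breakdown")
}

subsample_frames <- function(times, interval_ps) {
  if (interval_ps <= 0) return(seq_along(times))
  sel <- integer(0)
  last <- -Inf
  for (k in seq_along(times)) {
    if (times[k] - last >= interval_ps - 1e-9) {
      sel <- c(sel, k)
      last <- times[k]
    }
  }
  sel
}

#' Summary table of an energy breakdown (mean +/- SD, kJ/mol)
#' @param object energy_breakdown
#' @param ... unused
#' @export
summary.energy_breakdown <- function(object, ...) {
  rows <- c(e_vdw = "van der Waals", e_elec = "Electrostatic",
            g_polar = "Polar solvation", g_nonpolar = "SASA",
            total = "Total binding energy")
  data.frame(
    term = unname(rows),
    mean = vapply(names(rows), function(n) mean(object$terms[[n]]), numeric(1)),
    sd = vapply(names(rows), function(n)
      if (length(object$terms[[n]]) > 1) stats::sd(object$terms[[n]]) else 0,
      numeric(1)),
    row.names = NULL)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("MM-PBSA binding energy over", length(x$frames), "frame(s)",
      sprintf("(chains %s|%s)\n", x$chainA, x$chainB))
  s <- summary(x)
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s %10.2f +/- %.2f kJ/mol\n", s$term[i], s$mean[i], s$sd[i]))
  cat("  (-T dS term not evaluated)\n")
  invisible(x)
}

#' Residue-wise decomposition of the binding free energy
#'
#' Pairwise MM terms are split half to each partner atom; polar and
#' nonpolar per-atom splits come from the grid and SASA differences. Summed
#' per residue and averaged over frames; the per-component residue sums
#' reproduce the complex-level components exactly.
#'
#' @param traj,chainA,chainB,pb,sasa_cfg,frame_interval_ps as
#'   [binding_energy()]
#' @return list: `residues` data.frame (chain_id, res_seq, res_name, vdw,
#'   elec, polar, nonpolar, total), `breakdown` the energy_breakdown
#' @export
residue_decomposition <- function(traj, chainA, chainB, pb = pb_config(),
                                  sasa_cfg = sasa_config(),
                                  frame_interval_ps = 0) {
  bd <- binding_energy(traj, chainA, chainB, pb, sasa_cfg,
                       frame_interval_ps, keep_per_atom = TRUE)
  acc <- Reduce(`+`, bd$per_atom) / length(bd$per_atom)
  a <- bd$topology$atoms
  key <- paste(a$chain_id, a$res_seq, sep = ":")
  res_order <- !duplicated(key)
  agg <- rowsum(acc, key, reorder = FALSE)
  df <- data.frame(chain_id = a$chain_id[res_order],
                   res_seq = a$res_seq[res_order],
                   res_name = a$res_name[res_order],
                   stringsAsFactors = FALSE)
  df <- cbind(df, agg[match(key[res_order], rownames(agg)), , drop = FALSE])
  df$total <- df$vdw + df$elec + df$polar + df$nonpolar
  rownames(df) <- NULL
  list(residues = df, breakdown = bd)
}

#' Compare two binding-energy states (e.g. phosphorylated vs unmodified)
#'
#' DDG = mean2 - mean1 per component with SD propagated as
#' sqrt(SD1^2 + SD2^2).
#'
#' @param b1 reference energy_breakdown
#' @param b2 comparison energy_breakdown
#' @param allow_unequal_n set TRUE to compare breakdowns with different
#'   frame counts
#' @return data.frame term/ddg/sd
#' @export
compare_states <- function(b1, b2, allow_unequal_n = FALSE) {
  if (length(b1$frames) != length(b2$frames) && !allow_unequal_n)
    stop("breakdowns have different frame counts; ",
         "set allow_unequal_n = TRUE to compare anyway")
  s1 <- summary(b1); s2 <- summary(b2)
  data.frame(term = s1$term,
             ddg = s2$mean - s1$mean,
             sd = sqrt(s1$sd^2 + s2$sd^2))
}
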