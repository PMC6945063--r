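test_that("rigid toy complex recovers the closed-form vacuum interaction", {
  tc <- gen_toy_complex(toy_complex_spec())  # +1/-1 e at 10 Angstrom
  traj <- trajectory(tc, list(coords(tc)))
  # near-degenerate dielectrics suppress the reaction field
  pb <- pb_config(eps_solute = 1, eps_solvent = 1.0000001,
                  ionic_strength = 0, fine_spacing = 0.5)
  bd <- binding_energy(traj, "A", "B", pb = pb)
  s <- summary(bd)
  ref <- attr(tc, "reference_energy")
  expect_equal(s$mean[s$term == "Total binding energy"], ref,
               tolerance = 1e-3)
  expect_equal(bd$terms$e_elec[1] + bd$terms$e_vdw[1], ref, tolerance = 1e-9)
})

test_that("separated chains have negligible binding energy", {
  spec <- toy_complex_spec(atoms_per_chain = 3, charges_A = c(0.5, -0.5, 0),
                           charges_B = c(-0.5, 0.5, 0), separation = 45,
                           seed = 7)
  tc <- gen_toy_complex(spec)
  traj <- trajectory(tc, list(coords(tc)))
  bd <- binding_energy(traj, "A", "B")
  total <- summary(bd)$mean[5]
  expect_lt(abs(total), 0.1)
})

test_that("per-frame totals are exact component sums and duplicate frames give SD 0", {
  tc <- gen_toy_complex(toy_complex_spec(separation = 8))
  traj <- trajectory(tc, list(coords(tc), coords(tc)), times = c(0, 1))
  bd <- binding_energy(traj, "A", "B", pb = pb_config(fine_spacing = 0.5))
  expect_identical(bd$terms$total,
                   bd$terms$e_vdw + bd$terms$e_elec + bd$terms$g_polar +
                     bd$terms$g_nonpolar)
  expect_equal(summary(bd)$sd, rep(0, 5))
  expect_true(is.na(bd$entropy_term))
})

test_that("binding energy is invariant under swapping the chain labels", {
  tc <- gen_toy_complex(toy_complex_spec(atoms_per_chain = 2,
                                         charges_A = c(0.7, -0.2),
                                         charges_B = c(-0.6, 0.1),
                                         separation = 7, seed = 12))
  traj <- trajectory(tc, list(coords(tc)))
  pb <- pb_config(fine_spacing = 0.5)
  b1 <- summary(binding_energy(traj, "A", "B", pb = pb))
  b2 <- summary(binding_energy(traj, "B", "A", pb = pb))
  expect_equal(b1$mean, b2$mean, tolerance = 1e-9)
})

test_that("frame subsampling honors the evaluation interval", {
  tc <- gen_toy_complex(toy_complex_spec())
  frames <- replicate(11, coords(tc), simplify = FALSE)
  traj <- trajectory(tc, frames, times = seq(0, 10000, by = 1000))
  sel <- phosbind:::subsample_frames(traj$times, 5000)
  expect_equal(traj$times[sel], c(0, 5000, 10000))
  expect_error(binding_energy(trajectory(tc, frames[1], times = 5),
                              "A", "C"), "partition")
})

test_that("residue decomposition conserves every component", {
  tc <- gen_toy_complex(toy_complex_spec(atoms_per_chain = 2,
                                         charges_A = c(0.6, -0.2),
                                         charges_B = c(-0.5, 0.3),
                                         separation = 8, seed = 3))
  traj <- trajectory(tc, list(coords(tc)))
  dec <- residue_decomposition(traj, "A", "B",
                               pb = pb_config(fine_spacing = 0.5))
  s <- summary(dec$breakdown)
  sums <- colSums(dec$residues[, c("vdw", "elec", "polar", "nonpolar")])
  for (i in 1:4)
    expect_equal(unname(sums[i]), s$mean[i],
                 tolerance = 1e-6 * max(1, abs(s$mean[i])))
  expect_equal(sum(dec$residues$total), s$mean[5],
               tolerance = 1e-6 * max(1, abs(s$mean[5])))
})

test_that("symmetric one-atom chains split the Coulomb term evenly", {
  tc <- gen_toy_complex(toy_complex_spec())  # one atom per chain
  traj <- trajectory(tc, list(coords(tc)))
  dec <- residue_decomposition(traj, "A", "B",
                               pb = pb_config(fine_spacing = 0.5))
  el <- dec$residues$elec
  expect_equal(el[1], el[2])
  expect_equal(el[1], sum(el) / 2)
})

test_that("uncharged, non-contacting residues contribute nothing to MM terms", {
  tc <- gen_toy_complex(toy_complex_spec(atoms_per_chain = 2,
                                         charges_A = c(1, 0),
                                         charges_B = c(-1, 0),
                                         separation = 25, seed = 8))
  traj <- trajectory(tc, list(coords(tc)))
  dec <- residue_decomposition(traj, "A", "B",
                               pb = pb_config(fine_spacing = 1))
  r <- dec$residues
  uncharged <- r[r$res_seq == 2, ]
  expect_equal(uncharged$elec, c(0, 0))
  # LJ has no cutoff, so "no contacts" means negligibly small, not zero
  expect_true(all(abs(uncharged$vdw) < 1e-4))
})

test_that("state comparisons propagate uncertainties", {
  tc <- gen_toy_complex(toy_complex_spec(separation = 8))
  traj <- trajectory(tc, list(coords(tc)))
  pb <- pb_config(fine_spacing = 0.5)
  b <- binding_energy(traj, "A", "B", pb = pb)
  d0 <- compare_states(b, b)
  expect_equal(d0$ddg, rep(0, 5))

  # direct check of the propagation formula on synthetic summaries
  b1 <- b; b2 <- b
  b1$frames <- b2$frames <- 1:2
  b1$times <- b2$times <- 1:2
  for (nm in c("e_vdw", "g_polar", "g_nonpolar")) {
    b1$terms[[nm]] <- c(0, 0); b2$terms[[nm]] <- c(0, 0)
  }
  b1$terms$e_elec <- c(7, 13)    # mean 10
  b2$terms$e_elec <- c(22, 28)   # mean 25
  b1$terms$total <- b1$terms$e_elec
  b2$terms$total <- b2$terms$e_elec
  d <- compare_states(b1, b2)
  expect_equal(d$ddg[d$term == "Total binding energy"], 15)
  sd1 <- stats::sd(c(7, 13)); sd2 <- stats::sd(c(22, 28))
  expect_equal(d$sd[d$term == "Total binding energy"],
               sqrt(sd1^2 + sd2^2))
  # component DDGs sum to the total DDG
  expect_equal(sum(d$ddg[d$term != "Total binding energy"]),
               d$ddg[d$term == "Total binding energy"])

  b3 <- b
  b3$frames <- c(b$frames, b$frames)
  expect_error(compare_states(b, b3), "frame counts")
})
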