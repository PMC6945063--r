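test_that("generators are deterministic given spec and seed", {
  t1 <- gen_toy_complex(toy_complex_spec(atoms_per_chain = 4, seed = 9))
  t2 <- gen_toy_complex(toy_complex_spec(atoms_per_chain = 4, seed = 9))
  expect_identical(coords(t1), coords(t2))

  g1 <- gen_contact_trajectory(telegraph_spec(seed = 3))
  g2 <- gen_contact_trajectory(telegraph_spec(seed = 3))
  expect_identical(g1$series$distances, g2$series$distances)

  a1 <- gen_alignment(alignment_spec(n_sequences = 20, seed = 5))
  a2 <- gen_alignment(alignment_spec(n_sequences = 20, seed = 5))
  expect_identical(a1$seqs, a2$seqs)

  w1 <- gen_substrate_windows(n = 10, seed = 2)
  w2 <- gen_substrate_windows(n = 10, seed = 2)
  expect_identical(w1, w2)

  expect_lt(stream_seed(1, "telegraph"), 2^31)
  expect_false(stream_seed(1, "telegraph") == stream_seed(1, "alignment"))
})

test_that("Born fixture carries its closed-form energy", {
  s <- gen_born_system(1.0, 2.0)
  expect_equal(n_atoms(s), 1)
  expect_equal(total_charge(s), 1.0)
  expect_equal(attr(s, "born_energy")(2, 80), born_energy(1, 2, 2, 80))
  p <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(s, p)
  s2 <- read_pqr(p)
  expect_equal(s2$atoms$charge, 1.0)
  expect_equal(s2$atoms$radius, 2.0)
  expect_error(gen_born_system(1, -1), "radius")
})

test_that("toy complexes carry a brute-force interaction reference", {
  tc <- gen_toy_complex(toy_complex_spec())  # +1/-1 at 10 A
  lj_ref <- {
    sij <- 3.4; eij <- 0.3; r <- 10
    4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(attr(tc, "reference_coulomb"), -COULOMB_CONST / 10,
               tolerance = 1e-12)
  expect_equal(attr(tc, "reference_energy"), -COULOMB_CONST / 10 + lj_ref,
               tolerance = 1e-12)

  tc0 <- gen_toy_complex(toy_complex_spec(charges_A = 0, charges_B = 0))
  expect_equal(attr(tc0, "reference_coulomb"), 0)
  expect_equal(attr(tc0, "reference_energy"), attr(tc0, "reference_lj"))
})

test_that("telegraph process has the stated switching statistics", {
  # k_on = 0 starting unbound: no events ever
  g0 <- gen_contact_trajectory(telegraph_spec(k_on = 0, k_off = 0.5,
                                              n_frames = 500, seed = 1))
  expect_equal(nrow(g0$true_events), 0)
  expect_true(all(!g0$states))

  # k_on = k_off = 1 alternates deterministically
  g1 <- gen_contact_trajectory(telegraph_spec(k_on = 1, k_off = 1,
                                              n_frames = 6, seed = 1))
  expect_equal(g1$states, rep(c(TRUE, FALSE), 3))

  # stationary bound fraction ~ k_on / (k_on + k_off)
  sp <- telegraph_spec(k_on = 0.02, k_off = 0.03, n_frames = 1e5, seed = 17)
  g <- gen_contact_trajectory(sp)
  expect_lt(abs(mean(g$states) - sp$k_on / (sp$k_on + sp$k_off)), 0.02)

  # the series distances realize the states up to the configured noise
  expect_equal(as.numeric(tapply(g$series$distances, g$states, mean)),
               c(9.0, 4.5), tolerance = 0.01)
})

test_that("synthetic alignments realize the requested conservation", {
  aln <- gen_alignment(alignment_spec(n_sequences = 500,
                                      n_columns = 3, p = c(1, 0.05, 0.5),
                                      seed = 6))
  profs <- column_profiles(aln)
  expect_equal(unname(profs[[1]]$freq[attr(aln, "consensus")[1]]), 1)
  expect_equal(conservation_score(profs[[1]]), 9L)
  expect_lte(conservation_score(profs[[2]]), 1L)
})

test_that("substrate windows realize the generating PPM", {
  # degenerate PPM: all windows identical
  deg <- matrix(0, 20, 15, dimnames = list(AMINO_ACIDS, NULL))
  deg[cbind(match(strsplit("DEADLYSSLEDSALE", "")[[1]], AMINO_ACIDS), 1:15)] <- 1
  w <- gen_substrate_windows(deg, n = 5, seed = 1)
  expect_equal(unique(w), "DEADLYSSLEDSALE")

  # forced central serine
  w2 <- gen_substrate_windows(tbk1_like_ppm(), n = 50, seed = 2,
                              force_center_s = TRUE)
  expect_true(all(substr(w2, 8, 8) == "S"))

  # recovery: per-position total variation <= 0.05 at n = 1000
  wins <- gen_substrate_windows(n = 1000, seed = 9)
  m <- build_motif(data.frame(sequence = wins, site = 8), alpha = 0)
  tv <- vapply(1:15, function(p)
    0.5 * sum(abs(m$ppm[, p] - tbk1_like_ppm()[, p])), numeric(1))
  expect_lte(max(tv), 0.05)
})

test_that("tripeptide fixture is a valid parameterized peptide", {
  tri <- gen_tripeptide()
  expect_equal(total_charge(tri), 0)
  expect_true(all(tri$atoms$radius > 0))
  # no heavy-atom clashes in the extended conformation
  expect_gt(min(stats::dist(coords(tri))), 1.2)
})
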