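test_that("PDB reading preserves atoms and errors on malformed coordinates", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 2.0, 1.2, 0),
    "END"))
  s <- read_pdb(p)
  expect_equal(n_atoms(s), 3)
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(s$atoms$charge, rep(0, 3))
  expect_equal(coords(s)[2, 1], 1.46)

  bad <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(bad, c(
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    sub("   1.460", "  xx.xxx", pdb_atom_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0))))
  expect_error(read_pdb(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(empty, "END")
  expect_error(read_pdb(empty), "no ATOM")
})

test_that("multi-MODEL PDB returns first model with a warning", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, c(
    "MODEL     1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL     2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 5, 0, 0),
    "ENDMDL", "END"))
  expect_warning(s <- read_pdb(p), "MODEL")
  expect_equal(n_atoms(s), 1)
  expect_equal(coords(s)[1, 1], 0)
})

test_that("PQR round trip preserves charge and radius fields", {
  p <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 Q ION 1 0.0 0.0 0.0 1.0 2.0", p)
  s <- read_pqr(p)
  expect_equal(s$atoms$charge, 1.0)
  expect_equal(s$atoms$radius, 2.0)

  s2 <- make_atoms(c("C1", "O1"), "TOY", c(1L, 1L), "A",
                   rbind(c(0.123, -4.5, 6.789), c(3, 2, 1)),
                   charge = c(0.25, -0.75), radius = c(1.7, 1.52),
                   elem = c("C", "O"))
  out <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(s2, out)
  s3 <- read_pqr(out)
  expect_equal(s3$atoms$charge, s2$atoms$charge)
  expect_equal(s3$atoms$radius, s2$atoms$radius)
  expect_equal(coords(s3), coords(s2), tolerance = 1e-3)

  neg <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 Q ION 1 0.0 0.0 0.0 1.0 -2.0", neg)
  expect_error(read_pqr(neg), "radius")
})

test_that("parameter assignment covers residues, sums charges, is idempotent", {
  tri <- gen_tripeptide(c("GLY", "GLY", "GLY"), parameterize = FALSE)
  s <- assign_parameters(tri)
  expect_true(all(s$atoms$radius > 0))
  expect_equal(total_charge(s), 0)

  # SEP net charge equals the bundled table's column sum (independent read)
  tab <- utils::read.table(
    system.file("extdata", "ff_params.tsv", package = "phosbind"),
    header = TRUE, sep = "\t", comment.char = "#")
  sep_sum <- sum(tab$charge[tab$res_name == "SEP"])
  ps <- build_phosphoserine(gen_tripeptide(), "A", 2)
  rc <- residue_charges(ps)
  expect_equal(rc$charge[rc$res_name == "SEP"], sep_sum)
  expect_equal(sep_sum, -2)

  bad <- make_atoms("ZZ", "XYZ", 1L, "A", matrix(0, 1, 3), elem = "C")
  expect_error(assign_parameters(bad), "XYZ")

  s2 <- assign_parameters(s)
  expect_identical(s$atoms, s2$atoms)
})

test_that("trajectory I/O: multi-model PDB, congruence errors, bitwise TSV", {
  topo <- gen_tripeptide()
  p <- withr::local_tempfile(fileext = ".pdb")
  a <- topo$atoms
  model <- function(k, shift) c(
    sprintf("MODEL %5d", k),
    vapply(seq_len(nrow(a)), function(i)
      pdb_atom_line(a$serial[i], a$name[i], a$res_name[i], a$chain_id[i],
                    a$res_seq[i], a$x[i] + shift, a$y[i], a$z[i]),
      character(1)),
    "ENDMDL")
  write_toy_pdb(p, c(model(1, 0), model(2, 1), model(3, 2), "END"))
  traj <- read_trajectory(p, topo)
  expect_equal(n_frames(traj), 3)
  expect_equal(traj$frames[[3]][1, 1], topo$atoms$x[1] + 2, tolerance = 1e-3)

  bad <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(model(1, 0), model(2, 1), "END")
  lines <- lines[-20]  # drop one atom from frame 2
  write_toy_pdb(bad, lines)
  expect_error(read_trajectory(bad, topo), "frame 2")

  # coordinate-table round trip is bitwise exact
  frames <- list(coords(topo), coords(topo) + pi, coords(topo) * exp(1))
  tr <- trajectory(topo, frames, times = c(0, 0.1, 0.25))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, tsv)
  tr2 <- read_trajectory(tsv, topo)
  expect_identical(tr2$frames, tr$frames)
  expect_identical(tr2$times, tr$times)
})

test_that("B-factor maps write per-residue values with clamping", {
  s <- gen_tripeptide()
  p <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_map(s, c("A:1" = 1.5), p)
  reread <- suppressWarnings(bio3d::read.pdb(p))
  b <- reread$atom$b
  expect_equal(b[reread$atom$resno == 1], rep(1.5, sum(s$atoms$res_seq == 1)))
  expect_equal(b[reread$atom$resno == 2], rep(0, sum(s$atoms$res_seq == 2)))

  expect_warning(write_bfactor_map(s, c("A:1" = 12345), p), "clamped")
  reread <- suppressWarnings(bio3d::read.pdb(p))
  expect_equal(max(reread$atom$b), 999.99)

  expect_error(write_bfactor_map(s, c("B:9" = 1), p), "absent")
})

test_that("atom selection distinguishes side-chain heavy atoms", {
  s <- gen_tripeptide()
  sc <- atom_select(s, res_seq = 2, heavy = TRUE, sidechain = TRUE)
  expect_setequal(s$atoms$name[sc], c("CB", "OG"))
  gly <- gen_tripeptide(c("ALA", "GLY", "ALA"))
  expect_length(atom_select(gly, res_seq = 2, sidechain = TRUE), 0)
})
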