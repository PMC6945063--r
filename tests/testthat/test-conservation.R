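test_that("column profiles count residues, gaps and consensus correctly", {
  aln <- alignment(c(a = "AAG", b = "AAG", c = "-AG", d = "GAG"))
  profs <- column_profiles(aln)
  # column 1: A,A,-,G -> non-gap freq(A) = 2/3, gap fraction 1/4
  expect_equal(unname(profs[[1]]$freq["A"]), 2 / 3)
  expect_equal(profs[[1]]$gap_fraction, 0.25)
  expect_equal(profs[[1]]$consensus, "A")
  expect_equal(profs[[2]]$consensus, "A")
  expect_equal(unname(profs[[2]]$freq["A"]), 1)

  # 8 A vs 2 G
  aln2 <- alignment(setNames(c(rep("A", 8), rep("G", 2)), paste0("s", 1:10)))
  p2 <- column_profiles(aln2)[[1]]
  expect_equal(unname(p2$freq["A"]), 0.8)
  expect_equal(p2$consensus, "A")

  # consensus ties break alphabetically
  aln3 <- alignment(c(x = "G", y = "A"))
  expect_equal(column_profiles(aln3)[[1]]$consensus, "A")

  # all-gap column flagged
  aln4 <- alignment(c(x = "-A", y = "-A"))
  p4 <- column_profiles(aln4)[[1]]
  expect_equal(p4$gap_fraction, 1)
  expect_true(is.na(p4$consensus))
  expect_error(conservation_score(p4), "all-gap")

  expect_error(alignment(c(a = "AA", b = "AAA")), "unequal")
})

test_that("the 0-9 conservation score follows the entropy formula", {
  aln_cons <- alignment(setNames(rep("W", 50), paste0("s", 1:50)))
  expect_equal(conservation_score(column_profiles(aln_cons)[[1]]), 9L)

  # uniform over all 20 residues -> score 0
  aln_unif <- alignment(setNames(AMINO_ACIDS, paste0("s", 1:20)))
  expect_equal(conservation_score(column_profiles(aln_unif)[[1]]), 0L)

  # 50/50 split: H = 1 bit -> floor(9 (1 - 1/log2 20)) = 6
  aln_half <- alignment(setNames(c(rep("A", 5), rep("G", 5)), paste0("s", 1:10)))
  expect_equal(conservation_score(column_profiles(aln_half)[[1]]), 6L)
})

test_that("alignment reading handles FASTA and Stockholm", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "ACDEF", ">o1", "ACDEG"), fa)
  a1 <- read_alignment(fa)
  expect_equal(length(a1$seqs), 2)
  expect_equal(a1$reference, "ref")

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "ref  ACD-F", "o1   ACDEF", "//"), sto)
  a2 <- read_alignment(sto)
  expect_equal(nchar(a2$seqs[[1]]), 5)
  expect_equal(a2$ref_map, c(1, 2, 3, 5))
})

test_that("motif matrices follow the pseudocount and information content rules", {
  # identical windows, alpha = 0: IC = log2 20 at every position
  subs <- data.frame(sequence = rep("DEADLYSSLEDSALE", 4), site = 8)
  m <- build_motif(subs, alpha = 0)
  expect_equal(m$ic, rep(log2(20), 15))
  expect_equal(colSums(m$ppm), rep(1, 15))

  # two windows differing at one position vs a scripted count oracle
  subs2 <- data.frame(sequence = c("AAAAAAASAAAAAAA", "AAAAAAASAAAAAAG"),
                      site = 8)
  m2 <- build_motif(subs2, alpha = 0.01)
  want_p15 <- (c(A = 1, G = 1) + 0.01) / (2 + 20 * 0.01)
  expect_equal(unname(m2$ppm["A", 15]), unname(want_p15["A"]))
  expect_equal(unname(m2$ppm["G", 15]), unname(want_p15["G"]))
  expect_equal(unname(m2$ppm["W", 15]), 0.01 / (2 + 20 * 0.01))
  p <- m2$ppm[, 15]
  expect_equal(m2$ic[15], log2(20) + sum(p * log2(p)))

  # terminus windows are X-padded and excluded from counts
  m3 <- build_motif(data.frame(sequence = "SAAAAAAAA", site = 1), alpha = 0.01)
  expect_equal(sum(m3$counts[, 1]), 0)  # position 1 is padding
  expect_equal(unname(m3$counts["S", 8]), 1)
  expect_error(build_motif(data.frame(sequence = "AAA", site = 9)),
               "out of range")
})

test_that("information content is invariant under residue relabeling", {
  subs <- data.frame(sequence = c("ADKEACASRLLWSPE", "ADREACASRLLWSPA"),
                     site = 8)
  m <- build_motif(subs, alpha = 0.05)
  perm <- sample(AMINO_ACIDS)
  relabel <- chartr(paste(AMINO_ACIDS, collapse = ""),
                    paste(perm, collapse = ""), subs$sequence)
  m2 <- build_motif(data.frame(sequence = relabel, site = 8), alpha = 0.05)
  expect_equal(m2$ic, m$ic)
})

test_that("log-odds scores separate matching from background windows", {
  # motif = background gives score 0
  subs <- data.frame(sequence = "ADKEACASRLLWSPE", site = 8)
  m <- build_motif(subs, alpha = 0.01)
  m$ppm[] <- 1 / 20
  expect_equal(score_site("AAAAAAAAAAAAAAA", 8, m), 0)

  # all-X window scores 0
  m2 <- build_motif(subs, alpha = 0.01)
  expect_equal(score_site(strrep("X", 15), 8, m2), 0)

  # the motif's own window beats 100 random windows
  own <- score_site(subs$sequence, 8, m2)
  set.seed(21)
  rand <- replicate(100, score_site(
    paste(sample(AMINO_ACIDS, 15, replace = TRUE), collapse = ""), 8, m2))
  expect_true(own > max(rand))
})

test_that("relative accessibility tracks exposure", {
  # heavy-atom SASA against the all-atom-derived normalization: an exposed
  # extended residue sits high on the scale but below the all-atom maximum
  tri <- gen_tripeptide(c("ALA", "SER", "ALA"))
  rsa <- relative_accessibility(tri, "A:2")
  expect_gt(rsa$rsa, 60)
  expect_lt(rsa$rsa, 110)

  sh <- shell_fixture()
  # treat the central atom as a one-atom residue with an ALA normalization
  sh$atoms$res_name[1] <- "ALA"
  rsa0 <- relative_accessibility(sh, "A:1")
  expect_equal(rsa0$rsa, 0)

  # moving a blocking chain closer monotonically lowers RSA
  rsa_at <- function(offset) {
    blocker <- gen_tripeptide(c("ALA", "ALA", "ALA"), chain = "B",
                              parameterize = TRUE)
    bl <- blocker$atoms
    bl$x <- bl$x; bl$y <- bl$y + offset
    bl$serial <- bl$serial + 100L
    both <- param_structure(rbind(tri$atoms, bl))
    relative_accessibility(both, "A:2")$rsa
  }
  vals <- c(rsa_at(12), rsa_at(6), rsa_at(4))
  expect_true(all(diff(vals) < 0))

  expect_error(relative_accessibility(tri, "A:9"), "not in structure")
})

test_that("site annotation combines conservation, RSA and motif score", {
  aln <- gen_alignment(alignment_spec(n_sequences = 100, n_columns = 20,
                                      p = c(rep(1, 10), rep(0.3, 10)),
                                      seed = 3))
  seqref <- gsub("[-.]", "", aln$seqs[[aln$reference]])
  subs <- data.frame(sequence = rep(substr(seqref, 1, 15), 3), site = 8)
  motif <- build_motif(subs, alpha = 0.01)

  ann <- annotate_sites(seqref, aln = aln, structure = NULL, motif = motif,
                        sites = c(5, 8))
  expect_equal(ann$conservation[1], 9L)     # p = 1 column
  expect_true(all(is.na(ann$rsa)))          # no structure given
  expect_true(all(ann$flagged == TRUE))
  expect_false(any(is.na(ann$motif_score)))

  # compositional check against the piecewise operations
  profs <- column_profiles(aln)
  expect_equal(ann$conservation[2],
               conservation_score(profs[[aln$ref_map[8]]]))
  expect_equal(ann$motif_score[2], score_site(seqref, 8, motif))

  expect_error(annotate_sites(seqref, aln = aln, sites = 999),
               "out of sequence range")
})
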