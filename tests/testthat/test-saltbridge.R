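test_that("minimum side-chain distance matches constructed coordinates", {
  topo <- make_atoms(c("CA", "CB", "CA", "CB"), "TOY", c(1L, 1L, 2L, 2L),
                     "A", matrix(0, 4, 3), elem = c("C", "C", "C", "C"))
  frames <- list(
    rbind(c(-1, 0, 0), c(0, 0, 0), c(6, 0, 0), c(5, 0, 0)),
    rbind(c(-1, 0, 0), c(0, 0, 0), c(8, 0, 0), c(7, 0, 0)))
  traj <- trajectory(topo, frames)
  cs <- min_sidechain_distance(traj, "A:1", "A:2")
  expect_equal(cs$distances, c(5, 7))
})

test_that("multi-atom side chains reduce by the brute-force pair minimum", {
  set.seed(11)
  n1 <- 3; n2 <- 4
  topo <- make_atoms(
    c("CA", paste0("CB", 1:0)[1], "CG", "CD",
      "CA", "CB", "CG", "CD", "CE"),
    "TOY", c(rep(1L, 4), rep(2L, 5)), "A", matrix(0, 9, 3),
    elem = rep("C", 9))
  xyz <- matrix(rnorm(27, sd = 3), 9, 3)
  xyz[5:9, 1] <- xyz[5:9, 1] + 10
  traj <- trajectory(topo, list(xyz))
  cs <- min_sidechain_distance(traj, "A:1", "A:2")
  sc1 <- which(topo$atoms$res_seq == 1 & topo$atoms$is_sidechain)
  sc2 <- which(topo$atoms$res_seq == 2 & topo$atoms$is_sidechain)
  brute <- min(apply(expand.grid(sc1, sc2), 1, function(ij)
    sqrt(sum((xyz[ij[1], ] - xyz[ij[2], ])^2))))
  expect_equal(cs$distances, brute)
})

test_that("residues without side-chain heavy atoms are rejected", {
  gly <- gen_tripeptide(c("ALA", "GLY", "ALA"))
  traj <- trajectory(gly, list(coords(gly)))
  expect_error(min_sidechain_distance(traj, "A:1", "A:2"),
               "no side-chain heavy atoms")
})

test_that("formation events follow the crossing-entry rule at the cutoff", {
  ev <- count_formation_events(contact_series(c(8, 5.5, 5.8, 7, 5.9)))
  expect_equal(attr(ev, "n_formation"), 2)

  ev0 <- count_formation_events(contact_series(c(7, 7.5, 6.5)))
  expect_equal(attr(ev0, "n_formation"), 0)
  expect_equal(nrow(ev0), 0)

  ev1 <- count_formation_events(contact_series(c(5, 5, 7, 5)))
  expect_equal(attr(ev1, "n_formation"), 1)
  expect_equal(sum(ev1$initial_contact), 1)
  expect_equal(ev1$dwell[ev1$initial_contact], 2)

  # distance exactly at the cutoff counts as contact (closed boundary)
  evb <- count_formation_events(contact_series(c(7, 6.0, 7)))
  expect_equal(attr(evb, "n_formation"), 1)
})

test_that("event detection equals brute-force run enumeration", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- if (seed == 1) 1e4 else 1000
    d <- runif(n, 3, 9)
    dwell <- sample(c(1, 3, 10), 1)
    cs <- contact_series(d, cutoff = 6, dwell_min = dwell)
    got <- count_formation_events(cs)
    want <- brute_force_events(d, 6, dwell)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
    expect_equal(got$initial_contact, want$initial_contact)
    expect_equal(attr(got, "n_formation"), sum(!want$initial_contact))
  }
})

test_that("raising the cutoff never decreases the contact fraction", {
  set.seed(5)
  d <- runif(2000, 3, 9)
  cs <- contact_series(d)
  fr <- vapply(seq(3, 9, by = 0.5), function(co)
    contact_fraction(cs, co), numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("replica summaries pool event counts", {
  mk <- function(d) contact_series(d)
  lst <- list(mk(c(7, 5, 7)), mk(c(7, 7, 7)), mk(c(7, 5, 7, 5, 7)),
              mk(c(5, 5, 5)))
  summ <- summarize_replicas(lst)
  expect_equal(summ$per_replica$n_events, c(1, 0, 2, 0))
  expect_equal(summ$pooled, sum(summ$per_replica$n_events))
  expect_equal(summ$per_replica$contact_fraction[4], 1.0)
  expect_error(summarize_replicas(list()), "at least one")
})

test_that("telegraph detector calibration meets sensitivity and FDR bounds", {
  n_true <- 0; n_det <- 0; n_match <- 0
  for (i in 1:100) {
    g <- gen_contact_trajectory(telegraph_spec(seed = 1000 + i))
    ev <- count_formation_events(g$series, dwell_min = 10)
    ev <- ev[!ev$initial_contact, , drop = FALSE]
    te <- g$true_events
    n_true <- n_true + nrow(te)
    n_det <- n_det + nrow(ev)
    if (nrow(ev) > 0 && nrow(te) > 0)
      for (k in seq_len(nrow(ev)))
        if (any(ev$start_frame[k] <= te$end_frame &
                ev$end_frame[k] >= te$start_frame))
          n_match <- n_match + 1
  }
  expect_gt(n_true, 100)  # enough events for the rates to be meaningful
  expect_gte(n_match / n_true, 0.95)
  expect_lte((n_det - n_match) / max(n_det, 1), 0.05)
})
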