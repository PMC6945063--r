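# Salt-bridge contact dynamics: per-frame minimum side-chain heavy-atom
# distances, contact classification at a 6.0 Angstrom cutoff (0.6 nm, the
# stable-electrostatic-contact criterion), and formation-event counting
# over replicas.

#' Minimum side-chain heavy-atom distance time series for a residue pair
#'
#' Per frame, the minimum over all pairs of side-chain heavy atoms of the
#' two residues (backbone N/CA/C/O and hydrogens excluded). Residues
#' without side-chain heavy atoms (glycine) are an error.
#'
#' @param traj trajectory
#' @param resA,resB residues as `list(chain =, res_seq =)` or "A:93" strings
#' @param cutoff contact cutoff, Angstrom (default 6.0 = 0.6 nm)
#' @param dwell_min minimum run length (frames) for a formation event
#' @return object of class `contact_series`: data.frame-like list with
#'   `times` (ps), `distances` (Angstrom), pair metadata, `cutoff`,
#'   `dwell_min`
#' @export
min_sidechain_distance <- function(traj, resA, resB, cutoff = 6.0,
                                   dwell_min = 1) {
  resA <- parse_residue(resA); resB <- parse_residue(resB)
  s <- traj$topology
  ia <- atom_select(s, chain = resA$chain, res_seq = resA$res_seq,
                    heavy = TRUE, sidechain = TRUE)
  ib <- atom_select(s, chain = resB$chain, res_seq = resB$res_seq,
                    heavy = TRUE, sidechain = TRUE)
  for (nm in c("A", "B")) {
    idx <- if (nm == "A") ia else ib
    res <- if (nm == "A") resA else resB
    if (length(idx) == 0) {
      present <- atom_select(s, chain = res$chain, res_seq = res$res_seq)
      if (length(present) == 0)
        stop("residue ", res$chain, ":", res$res_seq, " not found")
      stop("residue ", res$chain, ":", res$res_seq, " (",
           s$atoms$res_name[present[1]],
           ") has no side-chain heavy atoms")
    }
  }
  d <- vapply(traj$frames, function(f)
    min_pair_distance(f[ia, , drop = FALSE], f[ib, , drop = FALSE]),
    numeric(1))
  name_of <- function(res, idx) s$atoms$res_name[idx[1]]
  structure(list(
    times = traj$times, distances = d,
    pair = list(A = c(resA, list(res_name = name_of(resA, ia))),
                B = c(resB, list(res_name = name_of(resB, ib)))),
    cutoff = cutoff, dwell_min = dwell_min), class = "contact_series")
}

parse_residue <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("residue string must be 'chain:res_seq'")
    list(chain = parts[1], res_seq = as.integer(parts[2]))
  } else list(chain = x$chain, res_seq = as.integer(x$res_seq))
}

#' Build a contact series directly from a distance vector
#'
#' @param distances per-frame minimum distances, Angstrom
#' @param times ps (default frame index)
#' @param cutoff Angstrom
#' @param dwell_min frames
#' @export
contact_series <- function(distances, times = seq_along(distances) - 1,
                           cutoff = 6.0, dwell_min = 1) {
  if (any(!is.finite(distances)) || any(distances <= 0))
    stop("distances must be positive and finite")
  structure(list(times = times, distances = distances, pair = NULL,
                 cutoff = cutoff, dwell_min = dwell_min),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("contact_series:", length(x$distances), "frames, cutoff",
      x$cutoff, "A; in contact",
      sprintf("%.1f%%", 100 * mean(x$distances <= x$cutoff)), "of frames\n")
  invisible(x)
}

#' Detect salt-bridge formation events in a contact series
#'
#' An event is a maximal run of frames with distance <= cutoff (closed
#' boundary) of length >= dwell_min that is entered by a crossing (the
#' previous frame was above the cutoff). A run starting at the first frame
#' has no entry crossing: it is reported with `initial_contact = TRUE` and
#' excluded from the formation count.
#'
#' @param series contact_series
#' @param cutoff,dwell_min override the series' stored values
#' @return data.frame: start_frame, end_frame (1-based), dwell,
#'   initial_contact; attribute `n_formation` holds the formation count
#' @export
count_formation_events <- function(series, cutoff = series$cutoff,
                                   dwell_min = series$dwell_min) {
  below <- series$distances <= cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= dwell_min
  ev <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                   dwell = r$lengths[keep])
  ev$initial_contact <- ev$start_frame == 1
  attr(ev, "n_formation") <- sum(!ev$initial_contact)
  ev
}

#' Fraction of frames in contact
#' @param series contact_series
#' @param cutoff Angstrom
#' @export
contact_fraction <- function(series, cutoff = series$cutoff) {
  mean(series$distances <= cutoff)
}

#' Summarize formation events over replicas
#'
#' Pools per-replica formation counts (one row per
#' simulated system, events summed over its replicas).
#'
#' @param series_list list of contact_series (one per replica)
#' @param cutoff,dwell_min overrides applied to every replica
#' @return list of class `replica_summary`: `per_replica` data.frame
#'   (replica, n_events, contact_fraction), `pooled` total event count
#' @export
summarize_replicas <- function(series_list, cutoff = NULL, dwell_min = NULL) {
  if (length(series_list) < 1) stop("need at least one series")
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    co <- if (is.null(cutoff)) s$cutoff else cutoff
    dm <- if (is.null(dwell_min)) s$dwell_min else dwell_min
    ev <- count_formation_events(s, co, dm)
    data.frame(replica = i, n_events = attr(ev, "n_formation"),
               contact_fraction = contact_fraction(s, co))
  })
  per_replica <- do.call(rbind, rows)
  structure(list(per_replica = per_replica,
                 pooled = sum(per_replica$n_events)),
            class = "replica_summary")
}

#' @export
print.replica_summary <- function(x, ...) {
  cat("replica_summary:", nrow(x$per_replica), "replicas,",
      "pooled salt-bridge formation events:", x$pooled, "\n")
  print(x$per_replica, row.names = FALSE)
  invisible(x)
}

#' Write a contact series as TSV (time_ps, distance_A, in_contact)
#' @param series contact_series
#' @param path output path
#' @export
write_contact_series <- function(series, path) {
  df <- data.frame(time_ps = fmt6(series$times),
                   distance_A = fmt6(series$distances),
                   in_contact = as.integer(series$distances <= series$cutoff))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(x) sprintf("%.6g", x)
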