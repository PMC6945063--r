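# Kinase-substrate sequence motif: a 15 x 20 position probability matrix
# built from substrate windows centered on the phosphosite (position 8),
# with per-position information content in bits and a log-odds site score.

MOTIF_WIDTH <- 15L
MOTIF_CENTER <- 8L   # 1-based center = phosphosite

#' Extract the 15-residue window around a site, X-padded at termini
#' @param sequence residue string
#' @param site 1-based site position
#' @return character vector of length 15
#' @export
site_window <- function(sequence, site) {
  n <- nchar(sequence)
  if (site < 1 || site > n)
    stop("site position ", site, " out of range for sequence of length ", n)
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- (site - 7):(site + 7)
  w <- ifelse(idx >= 1 & idx <= n, chars[pmax(pmin(idx, n), 1)], "X")
  w[!w %in% AMINO_ACIDS] <- "X"
  w
}

#' Build a kinase-substrate motif matrix from phosphosite windows
#'
#' Aligns the 15-residue fragments centered on each substrate's site
#' (position 8 = phosphosite), X-padding windows truncated by sequence
#' ends (padding excluded from counts). The position probability matrix is
#' (count + alpha) / (n_eff + 20 alpha) per position with n_eff the non-X
#' count; information content per position is log2(20) - H(PPM) bits.
#'
#' @param substrates data.frame with columns `sequence` and `site`
#'   (1-based), or a list of `list(sequence=, site=)`
#' @param alpha pseudocount (default 0.01)
#' @return object of class `motif_matrix`: `counts`, `ppm` (20 x 15),
#'   `ic` (bits, length 15), `alpha`, `n_windows`
#' @export
build_motif <- function(substrates, alpha = 0.01) {
  if (is.data.frame(substrates))
    substrates <- lapply(seq_len(nrow(substrates)), function(i)
      list(sequence = substrates$sequence[i], site = substrates$site[i]))
  if (length(substrates) < 1) stop("no substrate windows")
  windows <- lapply(seq_along(substrates), function(i) {
    s <- substrates[[i]]
    tryCatch(site_window(s$sequence, s$site),
             error = function(e) stop("substrate entry ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  counts <- matrix(0L, nrow = 20, ncol = MOTIF_WIDTH,
                   dimnames = list(AMINO_ACIDS, NULL))
  for (w in windows)
    for (p in seq_len(MOTIF_WIDTH))
      if (w[p] != "X") counts[w[p], p] <- counts[w[p], p] + 1L
  n_eff <- colSums(counts)
  if (alpha == 0 && any(n_eff == 0))
    stop("position(s) with no observed residues need alpha > 0")
  ppm <- sweep(counts + alpha, 2, n_eff + 20 * alpha, "/")
  ic <- apply(ppm, 2, function(p) {
    nz <- p[p > 0]
    log2(20) + sum(nz * log2(nz))
  })
  structure(list(counts = counts, ppm = ppm, ic = ic, alpha = alpha,
                 n_windows = length(windows)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cons <- AMINO_ACIDS[apply(x$ppm, 2, which.max)]
  cat("motif_matrix: 15 positions x 20 residues from", x$n_windows,
      "windows (alpha =", x$alpha, ")\n")
  cat("  consensus:", paste(cons, collapse = ""),
      " (center = position", MOTIF_CENTER, ")\n")
  cat("  IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' Log-odds motif score of a candidate site (bits)
#'
#' Sum over the 15 window positions of log2(PPM / background); X positions
#' (including terminus padding) contribute 0. A motif equal to the
#' background scores 0 for every window.
#'
#' @param sequence residue string
#' @param pos 1-based candidate site position
#' @param motif motif_matrix
#' @param background residue probability vector (default uniform 1/20)
#' @return score in bits
#' @export
score_site <- function(sequence, pos, motif, background = NULL) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  w <- site_window(sequence, pos)
  sc <- 0
  for (p in seq_len(MOTIF_WIDTH)) {
    if (w[p] == "X") next
    sc <- sc + log2(motif$ppm[w[p], p] / background[[w[p]]])
  }
  unname(sc)
}

#' Write a motif as a position-count TSV
#' @param motif motif_matrix
#' @param path output path
#' @export
write_motif_counts <- function(motif, path) {
  df <- data.frame(residue = rownames(motif$counts), motif$counts,
                   check.names = FALSE)
  names(df) <- c("residue", paste0("pos", seq_len(ncol(motif$counts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a motif in MEME minimal motif format
#' @param motif motif_matrix
#' @param path output path
#' @param name motif name
#' @export
write_meme <- function(motif, path, name = "motif1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste("ALPHABET=", paste(AMINO_ACIDS, collapse = "")), "",
               sprintf("MOTIF %s", name),
               sprintf(
                 "letter-probability matrix: alength= 20 w= %d nsites= %d",
                 ncol(motif$ppm), motif$n_windows)), con)
  for (p in seq_len(ncol(motif$ppm)))
    writeLines(paste(sprintf("%.6f", motif$ppm[, p]), collapse = " "), con)
  invisible(path)
}
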