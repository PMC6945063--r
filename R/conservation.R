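# Ortholog-alignment conservation: per-column residue frequencies and an
# entropy-based 0-9 conservation score. The 0-9 scale is a deterministic
# surrogate for phylogenetic rate-based scores (ConSurf-style): it uses
# only column composition, not the tree, and is labeled as such.

#' The 20 standard amino acids, alphabetical
#' @export
AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a multiple sequence alignment (aligned FASTA or Stockholm)
#'
#' @param path alignment file
#' @param format "fasta" or "stockholm"; guessed from the extension when
#'   NULL (`.sto`/`.stk` = Stockholm)
#' @param reference identifier of the query/reference row (default: first)
#' @return object of class `alignment`: `seqs` named character vector of
#'   equal-length gapped sequences, `reference`, `ref_map` (reference
#'   position -> column index)
#' @export
read_alignment <- function(path, format = NULL, reference = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(msa))
  alignment(seqs, reference = reference)
}

#' Construct an alignment object from gapped sequences
#' @param seqs named character vector of equal-length gapped sequences
#' @param reference identifier of the reference row (default: first)
#' @export
alignment <- function(seqs, reference = NULL) {
  if (length(seqs) < 1) stop("empty alignment")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  seqs <- toupper(seqs)
  if (is.null(reference)) reference <- names(seqs)[1]
  if (!reference %in% names(seqs))
    stop("reference '", reference, "' not in alignment")
  ref_chars <- strsplit(seqs[[reference]], "")[[1]]
  ref_map <- which(!ref_chars %in% c("-", "."))
  structure(list(seqs = seqs, reference = reference, ref_map = ref_map),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", length(x$seqs), "sequences x", nchar(x$seqs[[1]]),
      "columns; reference:", x$reference,
      "(", length(x$ref_map), "residues )\n")
  invisible(x)
}

aln_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), ""))
}

#' Per-column residue profiles of an alignment
#'
#' Frequencies are computed over non-gap symbols; `X` (unknown) is counted
#' but excluded from the consensus and from the entropy. Columns that are
#' entirely gaps get `gap_fraction = 1` and no consensus.
#'
#' @param aln alignment (>= 2 sequences)
#' @return list of per-column profiles: `counts` (named, 20 residues + X),
#'   `gap_fraction`, `freq` (over non-gap symbols), `consensus` (ties
#'   broken alphabetically; NA for all-gap), `n_nongap`
#' @export
column_profiles <- function(aln) {
  m <- aln_matrix(aln)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  symbols <- c(AMINO_ACIDS, "X")
  lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col[!col %in% c(symbols, "-", ".")] <- "X"
    gap <- col %in% c("-", ".")
    counts <- table(factor(col[!gap], levels = symbols))
    counts <- stats::setNames(as.integer(counts), symbols)
    n_nongap <- sum(!gap)
    freq <- if (n_nongap > 0) counts / n_nongap else counts * NA_real_
    aa_freq <- freq[AMINO_ACIDS]
    consensus <- if (n_nongap == 0 || all(aa_freq == 0)) NA_character_
      else AMINO_ACIDS[which.max(aa_freq)]  # which.max: first = alphabetical
    list(counts = counts, gap_fraction = mean(gap), freq = freq,
         consensus = consensus, n_nongap = n_nongap,
         low_confidence = mean(gap) > 0.5)
  })
}

#' Entropy-based conservation score on the 0-9 scale
#'
#' score = floor(9 (1 - H / log2 20)), with H the Shannon entropy (bits) of
#' the column's non-gap amino-acid frequencies (X excluded, renormalized).
#' A fully conserved column scores 9, a uniform column 0. This is a
#' composition-only surrogate for rate-based conservation scores.
#'
#' @param profile one element of [column_profiles()]
#' @return integer in 0..9
#' @export
conservation_score <- function(profile) {
  if (profile$gap_fraction >= 1 || profile$n_nongap == 0)
    stop("all-gap column has no conservation score")
  p <- profile$freq[AMINO_ACIDS]
  p <- p[p > 0]
  if (length(p) == 0) stop("column contains only unknown (X) residues")
  p <- p / sum(p)
  H <- -sum(p * log2(p))
  max(0L, min(9L, as.integer(floor(9 * (1 - H / log2(20))))))
}

#' Conservation scores for all columns of an alignment
#' @param aln alignment
#' @return integer vector (NA for all-gap columns)
#' @export
conservation_scores <- function(aln) {
  profs <- column_profiles(aln)
  vapply(profs, function(p)
    if (p$gap_fraction >= 1) NA_integer_ else conservation_score(p),
    integer(1))
}
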