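# Phosphosite annotation: relative solvent accessibility against a
# theoretical maxASA table, combined with alignment conservation and the
# kinase motif score.

#' Load the maximum-ASA normalization table
#' @param path TSV with columns res_name, max_asa; default: bundled
#'   theoretical Gly-X-Gly values (see file header for provenance)
#' @export
load_max_asa <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_asa.tsv", package = "phosbind")
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Relative solvent accessibility (%) of residues in a structure
#'
#' RSA = 100 x (residue SASA in the structure) / maxASA(residue type).
#' Values slightly above 100% can occur for exposed residues in extended
#' conformations (quadrature and table conventions differ).
#'
#' @param s param_structure with radii assigned
#' @param sites residues as "chain:res_seq" strings or a list of
#'   `list(chain=, res_seq=)`
#' @param sasa_cfg [sasa_config()]
#' @param max_asa_table from [load_max_asa()]
#' @return data.frame: chain_id, res_seq, res_name, asa (A^2), rsa (%)
#' @export
relative_accessibility <- function(s, sites, sasa_cfg = sasa_config(),
                                   max_asa_table = load_max_asa()) {
  if (!is.list(sites) || !is.null(sites$chain)) sites <- list(sites)
  sites <- lapply(sites, parse_residue)
  per_atom <- sasa(s, sasa_cfg)$per_atom
  rows <- lapply(sites, function(res) {
    idx <- atom_select(s, chain = res$chain, res_seq = res$res_seq)
    if (length(idx) == 0)
      stop("residue ", res$chain, ":", res$res_seq, " not in structure")
    rname <- s$atoms$res_name[idx[1]]
    asa <- sum(per_atom[idx])
    mx <- max_asa_table$max_asa[match(rname, max_asa_table$res_name)]
    if (is.na(mx)) stop("no maxASA entry for residue type ", rname)
    data.frame(chain_id = res$chain, res_seq = res$res_seq, res_name = rname,
               asa = asa, rsa = 100 * asa / mx, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate candidate phosphosites with conservation, RSA and motif score
#'
#' One record per site combining the alignment conservation score (0-9),
#' the relative solvent accessibility from the structure, and the log-odds
#' kinase-motif score. Partial data is tolerated and flagged: a site whose
#' residue is absent from the structure gets `rsa = NA`; a site mapping to
#' an all-gap alignment column gets `conservation = NA`.
#'
#' @param sequence the query residue string (must equal the alignment
#'   reference without gaps)
#' @param aln alignment whose reference is `sequence` (or NULL to skip)
#' @param structure param_structure with radii (or NULL to skip); residue
#'   numbers must correspond to sequence positions
#' @param motif motif_matrix (or NULL to skip)
#' @param sites integer sequence positions
#' @param chain chain of the sites in `structure`
#' @param sasa_cfg [sasa_config()]
#' @return data.frame: position, residue, conservation, rsa, motif_score,
#'   flagged
#' @export
annotate_sites <- function(sequence, aln = NULL, structure = NULL,
                           motif = NULL, sites, chain = "A",
                           sasa_cfg = sasa_config()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (any(sites < 1 | sites > length(chars)))
    stop("site position out of sequence range")
  profs <- NULL
  if (!is.null(aln)) {
    ref_ungapped <- gsub("[-.]", "", aln$seqs[[aln$reference]])
    if (toupper(ref_ungapped) != paste(chars, collapse = ""))
      stop("alignment reference sequence does not match `sequence`")
    profs <- column_profiles(aln)
  }
  rows <- lapply(sites, function(p) {
    cons <- NA_integer_
    if (!is.null(profs)) {
      col <- aln$ref_map[p]
      pr <- profs[[col]]
      if (pr$gap_fraction < 1) cons <- conservation_score(pr)
    }
    rsa <- NA_real_
    if (!is.null(structure)) {
      idx <- atom_select(structure, chain = chain, res_seq = p)
      if (length(idx) > 0)
        rsa <- relative_accessibility(
          structure, list(list(chain = chain, res_seq = p)), sasa_cfg)$rsa
    }
    ms <- if (!is.null(motif))
      score_site(paste(chars, collapse = ""), p, motif) else NA_real_
    data.frame(position = p, residue = chars[p], conservation = cons,
               rsa = rsa, motif_score = ms,
               flagged = is.na(cons) || is.na(rsa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
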