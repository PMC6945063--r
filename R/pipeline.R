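# Pipeline orchestration: a structured (YAML) config drives the stages
# simulate -> phospho -> [saltbridge | mmpbsa | conservation/motif/annotate],
# each writing TSV outputs with fixed 6-significant-digit formatting so
# identical configs give byte-identical files. A JSON manifest records the
# config snapshot, per-stage status, output inventory and checksums.

#' Default pipeline configuration
#'
#' Every model parameter is visible and overridable here: the PB block
#' (0.5 Angstrom fine grid, coarse box 1.5x the long axis, 150 mM, eps
#' 2/80), the SASA block (1.4 Angstrom probe, gamma 0.0226 kJ/mol/A^2,
#' offset 3.84 kJ/mol), the 6.0 Angstrom (0.6 nm) salt-bridge cutoff, the
#' 10 ns energy evaluation interval and the 15-residue motif window.
#'
#' @param seed global seed fanned out to generator streams
#' @param output_dir where stage outputs are written
#' @return nested configuration list
#' @export
default_config <- function(seed = 1, output_dir = "phosbind_out") {
  list(
    seed = seed,
    output_dir = output_dir,
    stages = c("simulate", "phospho", "saltbridge", "mmpbsa",
               "conservation", "motif", "annotate"),
    units = list(length = "angstrom"),
    inputs = list(structure = NULL, trajectory = NULL, alignment = NULL,
                  substrates = NULL),
    phospho = list(chain = "A", residues = list(2)),
    saltbridge = list(cutoff = 6.0, cutoff_unit = "angstrom", dwell_min = 1,
                      n_replicas = 6),
    pb = unclass(pb_config()),
    sasa = unclass(sasa_config()),
    mmpbsa = list(chainA = "A", chainB = "B", frame_interval_ps = 10000),
    motif = list(alpha = 0.01),
    annotate = list(sites = list(8), chain = "A"),
    simulate = list(
      telegraph = list(k_on = 0.005, k_off = 0.002, n_frames = 5000),
      toy_complex = list(atoms_per_chain = 3, separation = 8),
      alignment = list(n_sequences = 207, n_columns = 60),
      windows = list(n = 1000))
  )
}

#' Write the default configuration as YAML (`config init`)
#' @param path output YAML file
#' @param seed global seed recorded in the file
#' @export
write_default_config <- function(path, seed = 1) {
  yaml::write_yaml(default_config(seed = seed), path)
  invisible(path)
}

#' Read a pipeline configuration, filling unset keys with defaults
#' @param path YAML config file
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  modify_defaults(default_config(), user)
}

modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  known <- c("simulate", "phospho", "saltbridge", "mmpbsa", "conservation",
             "motif", "annotate")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (nm in c("structure", "trajectory", "alignment", "substrates")) {
    p <- cfg$inputs[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop("input file for '", nm, "' not found: ", p)
  }
  if (!cfg$units$length %in% c("angstrom", "nm"))
    stop("units$length must be 'angstrom' or 'nm'")
  invisible(cfg)
}

write_tsv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Stages run in dependency order; a stage failure is recorded in the
#' manifest and downstream stages are skipped. With no explicit inputs the
#' pipeline runs end-to-end on the synthetic fixture bundle produced by its
#' own `simulate` stage.
#'
#' @param config path to a YAML config, or a config list
#' @return manifest list (also written to `output_dir/manifest.json`);
#'   element `ok` is FALSE if any stage failed
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- if (is.character(config)) read_config(config) else
    modify_defaults(default_config(), config)
  validate_config(cfg)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(tool = "phosbind",
                   version = as.character(utils::packageVersion("phosbind")),
                   config = cfg, stages = list(), outputs = character(0))
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) {
      manifest$stages[[name]] <<- list(status = "skipped (not selected)")
      return()
    }
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped (upstream failure)")
      return()
    }
    t0 <- Sys.time()
    res <- tryCatch({
      files <- fun()
      list(status = "success", files = files,
           seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }, error = function(e) {
      failed <<- TRUE
      list(status = "failed", error = conditionMessage(e))
    })
    if (identical(res$status, "success"))
      manifest$outputs <<- c(manifest$outputs, res$files)
    manifest$stages[[name]] <<- res
  }

  run_stage("simulate", function() stage_simulate(cfg, out_dir, state))
  run_stage("phospho", function() stage_phospho(cfg, out_dir, state))
  run_stage("saltbridge", function() stage_saltbridge(cfg, out_dir, state))
  run_stage("mmpbsa", function() stage_mmpbsa(cfg, out_dir, state))
  run_stage("conservation", function() stage_conservation(cfg, out_dir, state))
  run_stage("motif", function() stage_motif(cfg, out_dir, state))
  run_stage("annotate", function() stage_annotate(cfg, out_dir, state))

  manifest$checksums <- as.list(tools::md5sum(
    manifest$outputs[file.exists(manifest$outputs)]))
  manifest$ok <- !failed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(manifest)
}

stage_simulate <- function(cfg, out_dir, state) {
  fx <- file.path(out_dir, "fixtures")
  dir.create(fx, showWarnings = FALSE)
  files <- character(0)
  seed <- cfg$seed

  born <- gen_born_system(1, 2)
  files <- c(files, write_pqr(born, file.path(fx, "born_ion.pqr")))

  tc_spec <- toy_complex_spec(
    atoms_per_chain = cfg$simulate$toy_complex$atoms_per_chain,
    charges_A = c(0.5, -0.5), charges_B = c(-0.5, 0.5),
    separation = cfg$simulate$toy_complex$separation,
    seed = stream_seed(seed, "toy_complex"))
  toy <- gen_toy_complex(tc_spec)
  state$toy <- toy
  files <- c(files, write_pqr(toy, file.path(fx, "toy_complex.pqr")))
  toy_traj <- trajectory(toy, list(coords(toy)))
  state$toy_traj <- toy_traj
  files <- c(files, write_trajectory(toy_traj, file.path(fx, "toy_traj.tsv")))

  reps <- lapply(seq_len(cfg$saltbridge$n_replicas), function(i)
    gen_contact_trajectory(telegraph_spec(
      k_on = cfg$simulate$telegraph$k_on,
      k_off = cfg$simulate$telegraph$k_off,
      n_frames = cfg$simulate$telegraph$n_frames,
      seed = stream_seed(seed, paste0("telegraph", i)))))
  state$replicas <- reps
  for (i in seq_along(reps))
    files <- c(files, write_contact_series(
      reps[[i]]$series, file.path(fx, sprintf("contact_rep%d.tsv", i))))

  aln <- gen_alignment(alignment_spec(
    n_sequences = cfg$simulate$alignment$n_sequences,
    n_columns = cfg$simulate$alignment$n_columns,
    seed = stream_seed(seed, "alignment")))
  state$aln <- aln
  aln_path <- file.path(fx, "ortholog_alignment.fasta")
  writeLines(paste0(">", names(aln$seqs), "\n", unname(aln$seqs)), aln_path)
  files <- c(files, aln_path)

  wins <- gen_substrate_windows(n = cfg$simulate$windows$n,
                                seed = stream_seed(seed, "windows"))
  subs <- data.frame(sequence = wins, site = MOTIF_CENTER)
  state$substrates <- subs
  files <- c(files, write_tsv6(subs, file.path(fx, "substrate_windows.tsv")))

  tri <- gen_tripeptide()
  state$tripeptide <- tri
  files <- c(files, write_pqr(tri, file.path(fx, "tripeptide.pqr")))
  files
}

pipeline_structure <- function(cfg, state) {
  if (!is.null(cfg$inputs$structure)) {
    p <- cfg$inputs$structure
    if (grepl("\\.pqr$", p, ignore.case = TRUE)) read_pqr(p)
    else assign_parameters(read_pdb(p))
  } else if (!is.null(state$tripeptide)) state$tripeptide
  else stop("no structure input and no simulate stage output")
}

stage_phospho <- function(cfg, out_dir, state) {
  s <- pipeline_structure(cfg, state)
  for (res in unlist(cfg$phospho$residues))
    s <- build_phosphoserine(s, cfg$phospho$chain, res)
  state$phospho_structure <- s
  write_pqr(s, file.path(out_dir, "phosphorylated.pqr"))
}

stage_saltbridge <- function(cfg, out_dir, state) {
  cutoff <- as_angstrom(cfg$saltbridge$cutoff, cfg$saltbridge$cutoff_unit)
  series_list <- if (!is.null(state$replicas))
    lapply(state$replicas, `[[`, "series")
  else stop("saltbridge stage needs the simulate stage (or trajectory input)")
  series_list <- lapply(series_list, function(s) {
    s$cutoff <- cutoff; s$dwell_min <- cfg$saltbridge$dwell_min; s
  })
  files <- character(0)
  ev_rows <- list()
  for (i in seq_along(series_list)) {
    ev <- count_formation_events(series_list[[i]])
    ev$replica <- i
    ev_rows[[i]] <- ev
  }
  ev_all <- do.call(rbind, ev_rows)
  ev_all$initial_contact <- as.integer(ev_all$initial_contact)
  files <- c(files, write_tsv6(ev_all, file.path(out_dir, "sb_events.tsv")))
  summ <- summarize_replicas(series_list)
  df <- summ$per_replica
  df$pooled_total <- summ$pooled
  files <- c(files, write_tsv6(df, file.path(out_dir, "sb_summary.tsv")))
  state$sb_summary <- summ
  files
}

stage_mmpbsa <- function(cfg, out_dir, state) {
  traj <- if (!is.null(cfg$inputs$trajectory)) {
    topo <- pipeline_structure(cfg, state)
    read_trajectory(cfg$inputs$trajectory, topo)
  } else if (!is.null(state$toy_traj)) state$toy_traj
  else stop("mmpbsa stage needs a trajectory input or the simulate stage")
  pb <- do.call(pb_config, cfg$pb)
  sc <- do.call(sasa_config, cfg$sasa)
  dec <- residue_decomposition(traj, cfg$mmpbsa$chainA, cfg$mmpbsa$chainB,
                               pb, sc,
                               frame_interval_ps = cfg$mmpbsa$frame_interval_ps)
  bd <- dec$breakdown
  state$breakdown <- bd
  files <- character(0)
  per_frame <- data.frame(frame = bd$frames, time_ps = bd$times,
                          e_vdw = bd$terms$e_vdw, e_elec = bd$terms$e_elec,
                          g_polar = bd$terms$g_polar,
                          g_nonpolar = bd$terms$g_nonpolar,
                          total = bd$terms$total)
  files <- c(files, write_tsv6(per_frame, file.path(out_dir, "mmpbsa_frames.tsv")))
  files <- c(files, write_tsv6(summary(bd), file.path(out_dir, "mmpbsa_summary.tsv")))
  files <- c(files, write_tsv6(dec$residues,
                               file.path(out_dir, "mmpbsa_residues.tsv")))
  vals <- stats::setNames(dec$residues$total,
                          paste0(dec$residues$chain_id, ":", dec$residues$res_seq))
  files <- c(files, write_bfactor_map(bd$topology, vals,
                                      file.path(out_dir, "mmpbsa_residues.pdb")))
  files
}

pipeline_alignment <- function(cfg, state) {
  if (!is.null(cfg$inputs$alignment)) read_alignment(cfg$inputs$alignment)
  else if (!is.null(state$aln)) state$aln
  else stop("conservation stage needs an alignment input or the simulate stage")
}

stage_conservation <- function(cfg, out_dir, state) {
  aln <- pipeline_alignment(cfg, state)
  state$aln_used <- aln
  profs <- column_profiles(aln)
  df <- data.frame(
    column = seq_along(profs),
    consensus = vapply(profs, function(p)
      ifelse(is.na(p$consensus), "-", p$consensus), character(1)),
    max_freq = vapply(profs, function(p)
      if (p$n_nongap > 0) max(p$freq[AMINO_ACIDS]) else NA_real_, numeric(1)),
    gap_fraction = vapply(profs, `[[`, numeric(1), "gap_fraction"),
    conservation = conservation_scores(aln))
  write_tsv6(df, file.path(out_dir, "conservation.tsv"))
}

pipeline_substrates <- function(cfg, state) {
  if (!is.null(cfg$inputs$substrates))
    utils::read.table(cfg$inputs$substrates, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else if (!is.null(state$substrates)) state$substrates
  else stop("motif stage needs a substrates input or the simulate stage")
}

stage_motif <- function(cfg, out_dir, state) {
  subs <- pipeline_substrates(cfg, state)
  motif <- build_motif(subs, alpha = cfg$motif$alpha)
  state$motif <- motif
  c(write_motif_counts(motif, file.path(out_dir, "motif_counts.tsv")),
    write_meme(motif, file.path(out_dir, "motif.meme")))
}

stage_annotate <- function(cfg, out_dir, state) {
  aln <- tryCatch(pipeline_alignment(cfg, state), error = function(e) NULL)
  struct <- tryCatch(pipeline_structure(cfg, state), error = function(e) NULL)
  motif <- state$motif
  seqchars <- if (!is.null(aln))
    gsub("[-.]", "", aln$seqs[[aln$reference]])
  else stop("annotate stage needs an alignment")
  sites <- unlist(cfg$annotate$sites)
  sites <- sites[sites <= nchar(seqchars)]
  if (length(sites) == 0) stop("no valid sites to annotate")
  # structure residues only join when numbering matches the sequence
  ann <- annotate_sites(seqchars, aln = aln, structure = struct,
                        motif = motif, sites = sites,
                        chain = cfg$annotate$chain)
  ann$flagged <- as.integer(ann$flagged)
  write_tsv6(ann, file.path(out_dir, "site_annotations.tsv"))
}

#' Render a Markdown report from a pipeline manifest
#'
#' Embeds the summary tables (the five binding-energy term rows,
#' pooled salt-bridge formation events, site annotations) and lists output
#' files.
#'
#' @param manifest manifest list from [run_pipeline()] or path to
#'   manifest.json
#' @param path output Markdown file (default: report.md next to the
#'   manifest outputs)
#' @return invisibly, the report path
#' @export
make_report <- function(manifest, path = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  if (length(manifest$stages) == 0) stop("empty manifest")
  out_dir <- manifest$config$output_dir
  if (is.null(path)) path <- file.path(out_dir, "report.md")
  ok <- vapply(manifest$stages, function(s)
    identical(s$status, "success"), logical(1))
  if (!any(ok)) stop("manifest records no successful stage")

  lines <- c("# phosbind run report", "",
             paste0("Tool version: ", manifest$version), "")
  lines <- c(lines, "## Stage status", "")
  for (nm in names(manifest$stages))
    lines <- c(lines, sprintf("- %s: %s", nm, manifest$stages[[nm]]$status))
  embed <- function(title, file) {
    p <- file.path(out_dir, file)
    if (!file.exists(p)) return(character(0))
    c("", paste("##", title), "", "```", readLines(p), "```")
  }
  lines <- c(lines,
             embed("Binding energy summary (kJ/mol)", "mmpbsa_summary.tsv"),
             embed("Salt-bridge formation events", "sb_summary.tsv"),
             embed("Site annotations", "site_annotations.tsv"))
  pdb <- file.path(out_dir, "mmpbsa_residues.pdb")
  if (file.exists(pdb))
    lines <- c(lines, "", "## Structure maps", "",
               paste0("- Residue-wise binding energy on B-factors: `", pdb, "`"))
  missing <- manifest$outputs[!file.exists(manifest$outputs)]
  if (length(missing) > 0)
    stop("declared outputs missing from disk: ",
         paste(missing, collapse = ", "))
  lines <- c(lines, "", "## Outputs", "",
             paste0("- `", manifest$outputs, "`"))
  writeLines(lines, path)
  invisible(path)
}
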