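Package: phosbind
Title: Phosphorylation Effects on Protein Complex Stability from Structure and Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how phosphorylation destabilizes protein-protein
    complexes, built around the analysis that links TBK1 phosphorylation of
    LC3C S93/S96 to loss of ATG4B binding. Provides MM-PBSA binding free
    energies over trajectory frames (inter-molecular Coulomb and
    Lennard-Jones terms, a finite-difference linearized Poisson-Boltzmann
    solver with grid focusing for polar solvation, and a Shrake-Rupley
    SASA model for the nonpolar term) with residue-wise decomposition;
    salt-bridge formation-event detection on minimum side-chain distance
    time series; phosphoserine building onto serine residues; ortholog
    alignment conservation scoring, kinase substrate motif matrices with
    information content, and relative solvent accessibility annotation of
    phosphosites. A synthetic-data module generates all fixtures (Born ions,
    toy two-chain complexes, telegraph contact trajectories, alignments and
    substrate windows) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
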