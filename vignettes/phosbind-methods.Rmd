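---
title: "Methods: continuum binding energetics, contact dynamics and phosphosite annotation in phosbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuum binding energetics, contact dynamics and phosphosite annotation in phosbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosbind)
```

# Scope and model

phosbind quantifies how phosphorylation destabilizes a protein--protein
complex, following the computational strategy used to show that
phosphorylation of LC3C at S93/S96 weakens binding to the ATG4B protease
and redirects the LC3C C-terminal tail through an intramolecular salt
bridge with R134. Four analysis layers are provided:

1. **MM-PBSA binding free energies** of a two-chain complex over
   trajectory frames, with residue-wise decomposition;
2. **salt-bridge formation dynamics**: minimum side-chain heavy-atom
   distance series, contact classification at 6.0 Å (0.6 nm), and
   formation-event counting over replicas;
3. **phosphoserine building** (SER → SEP, −2 e) onto existing structures;
4. **phosphosite annotation**: ortholog-alignment conservation, kinase
   substrate motif scores, and relative solvent accessibility.

A synthetic-data module generates every input with known ground truth, so
the full pipeline is testable without any external download.

# The MM-PBSA model

The binding free energy of a complex AB is estimated in the
single-trajectory scheme,

$$\Delta G_{\mathrm{bind}} = G_{AB} - G_{A} - G_{B},\qquad
G = \Delta E_{MM} + \Delta G_{\mathrm{solv}} - T\Delta S,$$

with $\Delta E_{MM} = \Delta E_{\mathrm{vdW}} + \Delta E_{\mathrm{elec}}$
(bonded terms cancel identically because receptor and ligand conformations
are extracted from the complex frames) and
$\Delta G_{\mathrm{solv}} = \Delta G_{\mathrm{polar}} +
\Delta G_{\mathrm{nonpolar}}$. The configurational entropy term
$-T\Delta S$ is **not evaluated**; it is reported as documented-absent and
never enters totals. Means and standard deviations are taken over frames
subsampled at a configurable evaluation interval (default 10 ns for
production data; the synthetic tests evaluate every frame).

## Molecular-mechanics terms

Inter-chain Coulomb and Lennard-Jones sums run over *all* atom pairs with
no distance cutoff — these are post-processing energies, not dynamics, and
a cutoff would add a free parameter. The Coulomb constant is
$f = 1389.35458$ kJ mol⁻¹ Å e⁻²; LJ parameters combine by
Lorentz–Berthelot rules.

## Polar solvation: finite-difference LPBE with focusing

The linearized Poisson–Boltzmann equation is discretized with the 7-point
conservative stencil on a regular grid:

* solute dielectric $\varepsilon_{\mathrm{in}} = 2$ inside the van der
  Waals volume (union of atom spheres, no probe rolling), solvent
  $\varepsilon_{\mathrm{out}} = 80$ outside; the face dielectric is
  harmonically interpolated over one grid cell across the surface, which
  centers the effective dielectric boundary and is what makes the Born
  test converge at the percent level;
* Debye–Hückel screening ($150$ mM, $\kappa$ from CODATA constants at the
  configured temperature) acts only outside the solute plus a 2 Å Stern
  ion-exclusion layer;
* charges spread onto the eight surrounding nodes by trilinear
  interpolation;
* a coarse solve (box edge 1.5× the solute long axis, with a floor so it
  always encloses the fine box plus margin) under analytic Debye–Hückel
  boundary values supplies the fine-grid boundary by interpolation
  (*focusing*); the fine grid uses 0.5 Å spacing by default;
* the solver is damped successive over-relaxation (ω = 1.8, deterministic,
  no random initialization) iterated to a relative residual of 1e-6; a
  non-converged solve is an error, never a silent result.

The polar energy is the reaction-field energy
$G = \tfrac12\sum_i q_i\,[\phi(\mathbf r_i) - \phi_{\mathrm{ref}}(\mathbf r_i)]$,
where $\phi_{\mathrm{ref}}$ is solved on the *identical* grid with a
uniform solute dielectric and no salt, so the grid self-energy cancels
exactly. For binding, complex and both isolated species are solved on one
shared grid with identical charge-to-grid mapping; discretization errors
of non-interacting atoms then cancel in
$\Delta\Delta G_{\mathrm{polar}} = G_{AB} - G_A - G_B$. On the Born ion
(q = 1 e, R = 2 Å, ε 2/80) the focused solve at 0.25 Å is within a
fraction of a percent of the closed form, with error magnitude decreasing
monotonically over 1.0 → 0.5 → 0.25 Å spacings.

The PB temperature defaults to 310 K, the production temperature of the
simulations the model emulates; 298 K is available through `pb_config()`.
The dielectric surface is the inflated van der Waals volume — the simplest
definition consistent with a 0.5 Å grid; molecular-surface construction is
deliberately out of scope.

## Nonpolar solvation

$G_{\mathrm{nonpolar}} = \gamma\,\mathrm{SASA} + b$ with
$\gamma = 0.0226$ kJ mol⁻¹ Å⁻² and $b = 3.84$ kJ/mol. SASA is computed by
Shrake–Rupley quadrature with a 1.4 Å probe on a deterministic
golden-spiral point set (960 points/atom by default; rotation invariance
is at the 0.5% quadrature level). In binding differences the offset $b$
cancels by construction
($\Delta\Delta G_{\mathrm{nonpolar}} = \gamma\,\Delta\mathrm{SASA}$),
because the offset is species-count dependent; it appears only in
per-species absolute values.

## Residue-wise decomposition

Pairwise MM terms are split half to each partner atom; polar and nonpolar
terms are split per atom by the grid reaction field and the SASA
difference. Per-residue sums reproduce the complex-level components to
1e-6 relative — this conservation is asserted in the tests, so the colored
structure maps (B-factor export) always add up to the reported totals.

# Salt-bridge formation events

The contact criterion is the minimum distance between side-chain heavy
atoms (side chain = everything but N, CA, C, O and hydrogens; glycine has
none and is rejected) at or below 6.0 Å — the 0.6 nm stable
electrostatic contact cutoff, with the boundary closed (exactly 6.0 Å
counts as contact) so event counts are bit-reproducible.

A **formation event** is a maximal run of contact frames of length
≥ `dwell_min` that is *entered by a crossing* (the previous frame was
above the cutoff). A run that starts at the first frame has no observed
crossing: it is reported, flagged `initial_contact`, and excluded from the
formation count. This convention reproduces the semantics of counting
zero events for a wild-type pair that never crosses, and makes the count
deterministic. `dwell_min` defaults to 1 frame; 10 frames is recommended
for noisy data and is what the calibration test uses. Replica summaries
pool formation counts over independent trajectories (six replicas in the
emulated study design).

No periodic-boundary minimum-image handling is performed; input
trajectories are assumed whole and unwrapped.

# Phosphoserine building

`build_phosphoserine()` renames SER → SEP, removes the hydroxyl hydrogen
if present, and grafts P, O1P, O2P, O3P with P–OG = 1.61 Å, terminal
P–O = 1.48 Å and tetrahedral geometry. The torsion about CB–OG is scanned
at 10° steps and the rotamer maximizing the minimum non-bonded heavy-atom
distance is kept. The residue is re-parameterized to a net charge of
−2 e — the fully deprotonated phosphate, the physiological-pH convention;
the protonation state is configurable through the parameter table since
the modeled study does not state the one used by its structure
preparation. All atoms outside the target residue are bitwise untouched.

# Conservation, motif and accessibility

**Conservation.** Column frequencies are computed over non-gap symbols
(`X` counted but excluded from consensus and entropy); columns with gap
fraction > 0.5 are flagged low-confidence. The 0–9 score is
$\lfloor 9\,(1 - H/\log_2 20)\rfloor$ with $H$ the Shannon entropy of the
column — a deterministic, composition-only surrogate for phylogenetic
rate-based scores (ConSurf-class methods need a tree and an external
service; this score does not, and is labeled as a surrogate wherever it
appears). "Normalized residue-conservation frequency" is operationalized
as the non-gap frequency.

**Motif.** 15-residue windows centered on the phosphosite (position 8)
build a position count matrix; windows truncated by a terminus are
X-padded and the padding excluded from counts, so sites within 7 residues
of an end remain usable. The PPM is
$(c + \alpha)/(n_{\mathrm{eff}} + 20\alpha)$, information content per
position $\log_2 20 - H$ bits, and candidate sites score as the log-odds
sum against a uniform background (X contributes 0).

**Accessibility.** RSA (%) normalizes residue SASA by the bundled
theoretical maximum-ASA table (Gly-X-Gly theoretical values; the SEP entry
is a synthetic estimate, marked as such in the file header). Because the
package computes SASA over heavy atoms while the normalization derives
from all-atom maxima, fully exposed residues plateau around 70–90% rather
than 100%; RSA remains a faithful *relative* exposure scale (burial drives
it monotonically to 0), which is what the site annotations use.

# Synthetic data: what it emulates, and what it does not

* `gen_born_system` / `gen_toy_complex`: charge systems with closed-form
  (Born) or brute-force (all-pairs Coulomb + LJ, computed by an
  independent double loop at generation time) reference energies.
* `gen_contact_trajectory`: a two-state telegraph process (bound mean
  4.5 Å, unbound 9.0 Å, Gaussian noise σ = 0.3 Å) with recorded switch
  frames. The calibration fixtures use per-frame switching probabilities
  k_on = 0.005, k_off = 0.002 over 5000 frames, giving dwell times well
  above the 10-frame threshold — emulating sub-microsecond stable contact
  formation with noise far from the cutoff (5σ from the bound state).
  Noise is uncorrelated frame to frame, the simplest null for calibrating
  the dwell threshold.
* `gen_alignment`: per-column conservation p (consensus with probability
  p, otherwise uniform over the remaining 19 residues). The recovery
  fixtures use 60 columns with p stepping 0.1…1.0 and 207–500 sequences,
  matching the scale of the emulated ortholog sets.
* `gen_substrate_windows` with `tbk1_like_ppm()`: i.i.d. draws from a
  sparse, position-specific generating PPM (1–3 preferred residues per
  position with a 5% tail; serine fixed at the center, leucine preferred
  at +1). Sparseness is deliberate: motifs estimated from tens of
  substrates concentrate probability on few residues per position, and a
  near-uniform column could not satisfy a ±0.05 total-variation recovery
  bound at n = 1000 for purely statistical reasons.

None of these emulate real force-field dynamics, correlated noise,
phylogenetic structure, or compositional biases of real proteomes. Passing
the recovery tests therefore demonstrates correctness of the estimators
and detectors under their stated models — not the accuracy of
microsecond-scale molecular dynamics, which is out of scope (the headline
binding energies of the original study derive from 1–7.4 μs simulations of
~54,000-atom systems and are not reproducible at desk scale; the package
validates against closed forms and ground-truth fixtures instead).

# Numerical choices and problem sizes

* Internal length unit is Å everywhere; the 0.6 nm cutoff is stored as
  6.0 Å, and config accepts explicit `nm`/`angstrom` unit keys.
* Residue numbering is preserved from the input file and never
  renumbered, so author numbering (S93, S96, R134) survives the pipeline.
* The bundled parameter table is a minimal self-contained fixed-charge set
  (20 amino acids, heavy-atom convention with hydrogen charges folded in,
  SEP at −2 e, monatomic ions) with integral residue charge sums — chosen
  so all energetics are reproducible from the repository alone; it is not
  a port of any published force field.
* Grid sizes in the test and acceptance workloads stay below ~1M nodes
  (fine boxes of 40–90 grid points per axis); the test suite's choices
  (toy complexes of 2–6 atoms, 100 telegraph replicas of 5000 frames,
  500-sequence alignments, 1000 windows) keep each property check in
  seconds to a couple of minutes on one CPU while leaving the estimators'
  statistics meaningful.
* TSV outputs round floats to 6 significant digits with fixed formatting,
  making identical runs byte-identical.
* Ties in consensus calling break alphabetically; the contact boundary is
  closed; SOR initialization is deterministic — every tie-break and
  boundary convention is fixed so that counts and scores are exactly
  reproducible.

# Known limitations

* The LPBE solver is linear only (no nonlinear PB), uses a vdW dielectric
  surface, and has no periodic electrostatics; generalized Born is not
  provided.
* MM-PBSA here is the single-trajectory variant; strain energy between
  bound and free conformations is not captured, and no entropy term is
  computed.
* The conservation score ignores phylogeny; deep or biased ortholog sets
  will compress its dynamic range relative to rate-based methods.
* The bundled charge set is a toy parameterization: suitable for method
  validation and for relative comparisons on prepared structures with
  matching conventions, not a replacement for a production force field.
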