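---
title: "Ensemble-docking virtual screening and assay analysis for OGT inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-docking virtual screening and assay analysis for OGT inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogtscreen)
library(dplyr)
```

## The problem

O-GlcNAc transferase (OGT) attaches N-acetylglucosamine from UDP-GlcNAc
onto serine/threonine residues of nuclear and cytoplasmic proteins.
Cell-permeable, low-toxicity OGT inhibitors are scarce, and
structure-based virtual screening against the UDP-binding pocket is a
practical route to new scaffolds. `ogtscreen` implements the
computational side of such a campaign as a reusable, testable pipeline:

1. **Property filter** — a natural-product library (SMILES/SDF) is
   reduced by four lead-likeness rules: 250 ≤ MW ≤ 600 Da, neutral and
   non-zwitterionic, 2–4 ring systems, ≥ 1 hydrogen-bond acceptor and
   ≥ 2 donors.
2. **Ensemble consensus ranking** — each surviving ligand is docked
   (externally; this package consumes Vina-style scores) against a
   16-member ensemble of OGT crystal structures (3PE3 … 5HGV). Per
   receptor the best (most negative) pose affinity is kept; the
   consensus score is the arithmetic mean over the ensemble, and the
   top 200 ligands go forward.
3. **Pose clustering** — each ligand's cross-ensemble poses, brought
   into one frame by Kabsch superposition of the receptors, are
   clustered by in-place RMSD; the biggest cluster's best-scoring
   member represents the ligand.
4. **Interaction triage** — geometric hydrogen-bond fingerprints
   against the pocket residues, with polar contact to the key residues
   (Gln839, Lys842, Thr921) as the necessary guideline, plus a
   pairwise per-residue interaction-energy decomposition for
   inspection.
5. **Assay analysis** — four-parameter-logistic (4PL) potency fitting
   of plate-reader dose–response data and Cheng–Prusoff analysis of
   IC50 versus substrate concentration to suggest the inhibition mode.

Because the compound library, the docking engine and the plate reader
are all external, every input has a seeded synthetic generator with
ground truth known by construction, so the whole pipeline is testable
offline.

## Models and conventions

### Property filter

* **Molecular weight** uses conventional (average) atomic masses over
  heavy atoms plus implicit/explicit hydrogens; tests use a 0.01 Da
  tolerance. Implicit hydrogens follow the standard lowest-valence
  model; aromatic atoms (trusted as drawn — lowercase SMILES or SDF
  bond type 4; no aromaticity perception is applied) reserve one
  valence unit for the ring system.
* **Ring systems** are connected components of the subgraph induced by
  ring bonds (bonds on at least one cycle, i.e. non-bridge edges), so
  fused and spiro assemblies sharing an atom count once and separated
  rings count individually. This matches the fused-assembly convention
  of lead-likeness servers; the source protocol does not define the
  term more precisely.
* **Donors/acceptors** follow the Lipinski-style convention the ≥1/≥2
  thresholds were designed around: donors are N/O atoms bearing ≥ 1
  hydrogen, acceptors are all N and O atoms. An option excludes
  pyrrole-type N–H nitrogens from the acceptor count.
* **Ionization** takes formal charges as drawn; there is no
  pH-dependent protonation model. A zwitterion carries mixed-sign
  atomic charges regardless of net charge.

All four rule flags are evaluated independently (no short-circuit), so
a report lists every violated rule. Unparsable library entries are
logged and skipped, never fatal.

### Consensus ranking

Affinities are Vina-style free-energy estimates in kcal/mol; "better"
means more negative, and the consensus mean is ranked ascending with
ties broken lexicographically by ligand id for determinism. The default
`"strict"` coverage mode excludes (with a warning) ligands lacking
scores on any ensemble member, mirroring a complete 16-receptor
campaign; `"available"` mode averages the receptors present and records
their number. The 22 × 22 × 22 Å search box centred on the Pro559
side-chain centroid is carried as metadata (`make_search_box()`); the
package never runs a docking search.

### Superposition and clustering

`kabsch_superpose()` computes the least-squares proper rotation via SVD
with the reflection branch resolved to det(+1); degenerate (collinear
or coincident) point sets are errors. Receptor-to-receptor alignment
pairs CA atoms common to both structures by (chain, residue number,
insertion code) — the standard reproducible common-core choice.
Pose–pose RMSD is computed in place (no refitting) and has no
symmetry correction (graph-automorphism-aware RMSD is a documented
non-goal). Clustering is single linkage realized as the connected
components of the ≤-threshold graph, with a default radius of 2.0 Å —
a conventional docking-pose cluster radius; the source protocol states
none. Biggest-cluster ties go to the cluster holding the most negative
affinity, and the representative is the best-scoring member (fallback:
lowest pose id).

### Interaction profiling

Hydrogen bonds use geometric criteria: donor–acceptor (N/O) distance
≤ 3.5 Å and donor–H–acceptor angle ≥ 120° where donor hydrogens are
resolved. Crystallographic receptors usually lack hydrogens, so donors
without them fall back to the distance-only criterion and the call is
flagged (`angle_checked = FALSE`). Polar contacts use a 4.0 Å N/O–N/O
cutoff, and a hydrogen bond always implies a polar contact. The triage
rule defaults to *any-of* {Gln839, Lys842, Thr921}: the protocol calls
these contacts a necessary guideline without stating whether all are
required, and it cites the threonine as 921 in its methods but 922 in
its results, so the residue set is fully configurable.

The per-residue energy decomposition sums, over (residue atom, ligand
atom) pairs within a 10 Å cutoff, a Coulomb term
`332.0636 · qi·qj / (ε·r)` (kcal/mol, charges in e, r in Å; dielectric
default 1.0, configurable) and a 12-6 Lennard-Jones term
`ε_ij ((r_min,ij/r)^12 − 2 (r_min,ij/r)^6)` with Lorentz–Berthelot
combination from a small element-keyed parameter table
(`lj_params()`); partial charges are always user-supplied. This is a
geometric pairwise surrogate for ranking pocket residues during triage
— it is **not** a binding free energy, and the package deliberately
computes no MM-PBSA-style quantities.

### Assay models

The 4PL uses the GraphPad-style inhibition convention
`y = bottom + (top − bottom)/(1 + (dose/IC50)^hill)` with hill > 0
meaning decreasing response, appropriate for activity normalized to a
vehicle control. The fit is bounded Levenberg–Marquardt least squares
on (bottom, top, log IC50, hill) with defaults bottom ∈ [−0.1, 0.5],
top ∈ [0.5, 1.5], IC50 ∈ [min dose/10, max dose×10], hill ∈ [0.1, 10];
fitting log IC50 keeps the dose scale well conditioned. Starts are
deterministic: top/bottom from extreme-dose means, IC50 from the dose
bracketing half-maximum, hill 1. A curve whose extreme-dose decline is
within noise (≤ max(0.05, 2·residual SD)) is flagged right-censored
with IC50 bounded below by the top tested dose rather than "fitted".

Inhibition modes use the standard reversible-inhibition rate laws and
their Cheng–Prusoff IC50 relations: competitive `Ki(1 + S/Km)`,
uncompetitive `Ki(1 + Km/S)`, noncompetitive `Ki`, mixed
`Ki(S + Km)/(Km + S/α)`. Fractional activity under each law is exactly
a hill-1 4PL in inhibitor dose, which the round-trip tests exploit: a
4PL fitted to mechanistic curves must reproduce the closed-form
IC50(S). No automatic mechanism-selection criterion is implemented —
the experimental observation this mirrors (IC50 flat below ~25 µM
substrate, rising above) has no stated quantitative model, so the
package compares candidate modes rather than electing one.

## The synthetic generators

All generators hang off one `generator_spec(seed = …)`; each draws
from its own stream derived from the top-level seed by a fixed offset,
so adding a generator never perturbs another, and identical specs give
identical output.

* `gen_library()` assembles molecules compositionally: cyclohexane
  scaffolds set the ring-system count, hydroxyls the donor count,
  methoxy groups extra acceptors, ammonium/carboxylate tails the
  ionization, and a methylene tail tunes the weight into or out of the
  250–600 Da window. Formula bookkeeping runs alongside the SMILES
  string, so every descriptor's true value is recorded independently
  of the parser that later measures it. Per-rule pass fractions are
  configurable; infeasible demands (more substituents than scaffold
  slots) are errors.
* `gen_score_matrix()` plants actives at Normal(−9.0, 0.5) kcal/mol
  among decoys at Normal(−6.0, 1.0), adds receptor-level jitter
  (SD 0.25) and strictly positive pose offsets, so the first pose per
  pair is the best by construction. Defaults mirror the campaign
  scale: 16 receptors, 4234 decoys, 10 actives, top-200 selection.
* `gen_toy_complex()` places the five pocket residues (Asn557, Gln839,
  Lys842, His920, Thr921) on a ring with polar side-chain atoms
  pointing inward and plants ligand hydroxyls at exact
  distance/angle geometry for each requested contact, plus jittered
  pose clouds and displaced outliers for clustering tests.
* `gen_assay_data()` simulates the potency experiment at the 8-point
  0.25–500 µM log grid with a planted IC50 of 21.8 µM (the study
  compound's measured potency), triplicates, and multiplicative
  mean-one lognormal noise at 5% CV — matching a plate assay reported
  as mean ± s.e.m. with n = 3 — plus a kinetic series over the
  2–400 µM substrate grid. Kinetic defaults (Ki 10 µM, Km 20 µM) are
  round numbers of the right magnitude for a UDP-GlcNAc-site
  inhibitor; the source reports no Km.

What the generators deliberately do **not** emulate: real chemistry
(3D conformers, tautomers, synthesizability), real protein folds (the
pocket is a toy ring), or docking-score physics (scores are Gaussian
draws). Passing tests therefore demonstrate that the pipeline's
*computations* are correct and its selections recover planted signal —
not that the protocol would re-discover a particular inhibitor from a
real library.

## Numerical choices and degenerate inputs

* Kabsch refuses n < 3 or rank-deficient (collinear) point sets; the
  SVD reflection branch is tested against mirror-image inputs.
* RMSD clustering of a single pose returns one singleton cluster
  without invoking the clustering backend.
* Consensus ranking of an empty score table returns an empty,
  correctly typed table; an empty library yields a zero-count report.
* The energy decomposition skips coincident atoms (r = 0) rather than
  returning infinities, and errors on atoms lacking charges or LJ
  parameters, naming the first offender.
* All report tables are written as TSV with fixed column order, so
  re-running an identical configuration is byte-reproducible (the
  provenance block carries a config hash; timestamps live only in the
  in-memory report object).

## Problem sizes used in the checks

The packaged checks run the filter fidelity on a 1,000-molecule
planted library; consensus-vs-oracle equivalence on 1,000 random score
tables; active recovery at the full campaign scale (4,234 decoys + 10
actives × 16 receptors) over 100 seeds; the Kabsch-vs-quaternion
comparison on 1,000 random instances; energy conservation and
hydrogen-bond recovery on 100 toy complexes; and potency recovery over
50 noisy replicated experiments for each of three planted potencies
(21.8 and 20.2 µM for the study compound in two assay formats, 3.5 µM
for the reference inhibitor). These sizes make the statistical
assertions sharp while keeping a full run on one CPU in minutes.

## A worked miniature

```{r mini}
spec <- generator_spec(seed = 1, library = list(n = 200),
                       scores = list(n_decoys = 195, n_actives = 5,
                                     ensemble = paste0("R", 1:4)))
lib <- gen_library(spec)
scores <- gen_score_matrix(spec)
# attach generated scores to the library ids
map <- setNames(lib$truth$id, unique(scores$scores$ligand_id))
scores$scores$ligand_id <- unname(map[scores$scores$ligand_id])

report <- filter_library(lib$molecules)
ranked <- consensus_rank(scores$scores)
head(select_top_k(ranked, 5), 5)[, 1:4]

fit <- fit_4pl(gen_assay_data(spec)$potency)
fit
tidy(fit)
```

## Known limitations

* The SMILES reader covers the organic subset plus bracket atoms,
  charges and ring closures — the dialect the generators emit and
  screening libraries commonly use — not full OpenSMILES (no isotopes
  in descriptors, stereo parsed but ignored).
* Descriptor counts depend on the drawn structure (charges, aromatic
  flags); no standardization/tautomer canonicalization is applied, by
  design.
* The headline campaign numbers of the original screen (61,000 library
  entries → 4,234 filtered) depend on an external library and
  additional server-side property predictions beyond the four stated
  rules; they are not reproducible from the rules alone and the
  package does not claim them.
* Pose RMSD has no symmetry correction; heavily symmetric ligands may
  over-estimate cluster spread.
* The per-residue decomposition is a triage heuristic; its values
  should never be quoted as binding free energies.
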