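---
title: "Methods: desk-scale structural off-target screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale structural off-target screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtargetr)
```

# The problem

A drug designed against one protein often binds others. When the off-targets
are numerous and the individual affinities weak — the situation for an
HIV-protease inhibitor binding members of the protein-kinase superfamily —
the interesting question is not a single docking score but a pipeline-level
judgment: which pockets across a structural proteome resemble the primary
binding site, do transferred ligand poses survive steric and statistical
scrutiny, what do ensemble-averaged free energies say, and what would
inhibiting the surviving set do to the signalling network downstream?

`offtargetr` implements that chain of reasoning as five composable stages
with deterministic synthetic inputs, so every statistical and numerical claim
the pipeline makes can be tested against an independent oracle on a desk-scale
machine. It does not run docking engines or molecular dynamics; it consumes
structures and snapshot ensembles (multi-MODEL PDB) and produces the
statistics around them.

# Binding-site representation

Receptors are reduced to their C-alpha trace. Burial is summarized by a
*geometric potential* (GP): the raw score of residue $i$ is
$g_i = \sum_{j \ne i,\, d_{ij} < d_c} (1 - d_{ij}/d_c)$ with a neighbour
cutoff $d_c = 10$ Å, min–max scaled to $[0, 100]$ per structure (an all-equal
profile maps to 50). This surrogate is rotation-invariant and monotone in
packing density — buried residues score high — and each residue carries a
unit vector toward its neighbour centroid as a cheap orientation descriptor.
The exact functional form of the potential is this package's own definition;
it is deliberately simple enough to be re-derived in a test.

A binding site is the set of receptor residues with any heavy atom strictly
within 5.0 Å of any ligand heavy atom (hydrogens ignored; crystallographic
inputs rarely have them). Site overlap between a known and a predicted site
is normalized by the known site, matching the convention of quoting
"16/22 = 73%"-style recovery.

# Order-independent alignment and its statistics

Two sites are aligned without regard to sequence order on a correspondence
graph. A vertex is a residue pair $(i \in A, j \in B)$ with weight

$$w_{ij} = S(aa_i, aa_j)/S_{\max} + \lambda\,(1 - |GP_i - GP_j|/100),$$

$S$ = BLOSUM62, $S_{\max} = 11$ its largest diagonal entry, $\lambda = 1$;
vertices below $w_{\min} = 0.4$ are dropped. Edges join vertices whose
intra-site C-alpha distances agree within $\varepsilon = 1.5$ Å. The
alignment is the maximum-weight clique: exact branch-and-bound up to 30
vertices, greedy seed-and-extend with 32 deterministic best-first restarts
beyond. Ties break to the lexicographically smallest pair list so results
are reproducible. The paired residues then define a Kabsch superposition
(proper rotation, determinant +1). The exact solver is validated against a
full enumeration of injective, geometrically consistent mappings on sites of
up to 6 residues.

Screening significance uses the Gumbel (type-I extreme-value) distribution,
the natural law for best-of-many alignment scores. The background is built
by aligning the query to *GP-preserving residue-label shuffles* of library
sites: geometry stays realistic while the chemical signal is destroyed. The
model is fitted by maximum likelihood from a method-of-moments start, and
$p = 1 - \exp(-\exp(-(s-\mu)/\beta))$ with tiers at $p < 10^{-3}$
(significant) and $p < 10^{-4}$ (stringent). Both thresholds are
configuration, not constants.

# Pose transfer, clashes, and the normalized docking score

A query ligand is carried into a target frame by the inverse of the
site-alignment transform, then rigid-body optimized (coordinate descent over
3 translations + 3 rotations, bounded to 5 Å of displacement — a local
search by contract, not a global pose search; ligand torsions are out of
scope). The interaction score is deliberately plain physics — LJ 12-6,
Coulomb with distance-dependent dielectric $\epsilon(r) = 4r$, and a
−1 kcal/mol bonus per N/O–N/O contact within 3.5 Å — because the pipeline's
contribution is the *filter logic*, not the scoring function; externally
computed scores can be imported via TSV and normalized identically.

The normalized docking score is a z-score against decoys:
$\mathrm{NDS} = (s - \bar{s}_{bg})/\sigma_{bg}$, background = the same
ligand placed randomly around the pocket (n = 50, seeded). Any affine
recalibration applied jointly to score and background cancels exactly, which
is the point: systematic engine bias disappears. Hits with NDS > 0 dock
worse than random molecules and are removed, as are hits with any heavy-atom
pair under 1.5 Å (the severe-clash geometric test; whether "severe clash"
should be a score or geometry test is genuinely open — geometry was chosen
for testability, with the threshold configurable).

Hydrogen bonds in contact reports are distance-only (donor/acceptor N/O
heavy atoms ≤ 3.5 Å): poses routinely lack hydrogens, so an angular term
would be theater. This is a documented limitation.

# Ensemble MM/GBSA

Binding free energy is assembled as
$\Delta G = \Delta H - T\Delta S$ with
$G = E_{MM} + G_{GB} + G_{SA} - TS$ per state, every binding term computed
as complex − receptor − ligand, and receptor/ligand coordinates sliced from
the complex snapshot (single-trajectory convention — intramolecular terms
cancel exactly in the difference, which a test asserts term by term).

* $E_{MM}$: harmonic bonds and angles, cosine torsions, LJ 12-6 and Coulomb
  ($\epsilon_{in} = 1$) over non-excluded pairs, 1-4 pairs scaled by 0.5
  (vdW) and 1/1.2 (electrostatics), no distance cutoff — cutoffs belong to
  the MD engine that produced the snapshots, not to rescoring.
* $G_{GB}$: OBC generalized Born. Effective radii come from pairwise
  descreening integrals with the tanh rescaling (coefficients 1.0, 0.8,
  4.85; offset 0.09 Å); the energy is the full double sum over
  $q_iq_j/f_{GB}$ including self terms, $\epsilon_{in} = 1.0$,
  $\epsilon_{out} = 78.5$, zero ionic strength (salt belongs to the MD
  setup). The isolated-ion limit reproduces the Born formula exactly when
  the effective radius is pinned, and at large separation a two-ion system
  decays to the summed Born terms plus the analytic screened-Coulomb cross
  term $-(1 - 1/\epsilon_{out})\,k_C q_1 q_2/r$ — both are asserted. Note
  that at 100 Å this cross term is still ~2% of the self terms for unit
  charges; the pure far-field band (< 1%) is checked at 400 Å.
* $G_{SA} = \gamma \cdot \mathrm{SASA}$ with $\gamma = 0.0072$
  kcal·mol⁻¹·Å⁻² and LCPO surface areas (probe 1.4 Å, hydrogens zero,
  per-atom areas clamped at zero). LCPO parameters for the synthetic atoms
  were calibrated by linear least squares against Monte-Carlo
  sphere-sampling SASA on a training set of randomly grown clusters — the
  same procedure by which LCPO tables are classically derived — with
  parameter classes indexed by overlap-neighbour count and burial fraction.
  On held-out clusters the total-SASA error is below 5% (mean below 1%).
* $-T\Delta S$: normal-mode analysis on each state after gas-phase
  minimization. The Hessian is built by central finite differences of the
  analytic MM gradient (step $10^{-4}$ Å), mass-weighted, and projected
  against the translational/rotational subspace; modes below
  $10^{-6}$ kcal·mol⁻¹·Å⁻²·amu⁻¹ (≈ 0.2 cm⁻¹) are treated as residual
  external or free-rotor modes and excluded — the harmonic-oscillator
  entropy diverges as $\omega \to 0$, so keeping them would make the result
  noise-dominated. Genuinely negative leftover curvatures are dropped with a
  warning. Translation uses Sackur–Tetrode at 1 atm and 298 K; rotation the
  classical rigid rotor from the inertia tensor. The minimization before the
  Hessian uses ε = 1 gas-phase electrostatics (the dielectric used there is
  unstated in standard protocols; plain gas phase was chosen and is
  documented here).

The five-stage restrained minimization protocol mirrors standard practice:
hydrogens; + waters (skipped when none); + side chains; all atoms with
backbone-and-ligand restraints at k = 4.0 kcal·mol⁻¹·Å⁻²; unrestrained —
all conjugate gradient, with a divergence guard. The pre-Hessian refinement
additionally uses a quasi-Newton polish, since NMA needs a much tighter
minimum than the protocol's stopping rule.

Ensemble averaging is plain arithmetic over snapshots — enthalpy on every
frame, entropy on a configurable stride (cost control; the stride a
production protocol would use is not standardized) — with standard errors of
the means. Stability diagnostics run alongside: PASS requires the maximum
backbone RMSD below 3.0 Å over the analysis window; a ligand whose mean
RMSD exceeds 4.0 Å or whose centroid leaves the 5.0 Å pocket envelope in
more than half the frames is flagged POCKET_EXIT. RMSD fitting uses
backbone N, CA, C, O by default (the exact backbone set is a convention
choice; it is configurable).

# Signed-network propagation

The downstream stage is deliberately qualitative: a typed, signed graph
(off-targets, intermediate proteins, pathways, cellular effects; edges
activation / inhibition / dual). Inhibiting an off-target injects `down`;
activation preserves a signal, inhibition flips it, dual makes it `mixed`;
a node aggregates incoming signals by the lattice join
`unknown < {up, down} < mixed`, computed as a monotone fixpoint so cyclic
graphs terminate. On DAGs this provably coincides with enumerating all
simple paths and aggregating sign products, which is exactly how the test
oracle (via igraph) checks it on random graphs. No kinetics, no weights:
edge semantics beyond sign are not knowable at this level of description,
and the package does not pretend otherwise.

The bundled edge list wires kinase off-targets (EGFR, IGF1R, FAK, Abl, FGFR,
EPHB4, ARK, PDK1, Akt2, CDK2) through PI3K/PIP3/Akt/Ras intermediates into
the PI3K/Akt, MAPK, JNK, NF-κB, mTOR, glucose-uptake and glycogenolysis
pathways and their cellular effects. It is a hand-curated illustration of
that topology for demonstrations and tests, not a ground-truth pathway
database.

# The synthetic data generator

`makeSyntheticComplex()` builds a concave shell of C-alpha atoms (plus one
outward side-chain dummy per residue) on a spherical cap covering 70% of a
sphere, radius `2.5 + pocketDepth` Å (default pocket depth 4 Å, enlarged as
needed to keep the fold self-avoiding at ~3.9 Å C-alpha spacing), and grows
a ligand chain (1.45 Å steps, elements cycling C/C/N/O) inside the pocket,
seeded near the wall so the 5.0 Å site is never empty, with every
receptor–ligand heavy-atom pair at least 2.5 Å apart.
`syntheticForcefield()` emits a matching parameter block whose bond and
angle rest values are taken from the generated geometry, so each complex
sits near its own gas-phase minimum — convenient for minimization and NMA
tests. `perturbEnsemble()` emulates MD snapshots as i.i.d. Gaussian
coordinate noise (default σ = 0.25 Å in the pipeline, a typical
equilibrated-trajectory fluctuation scale) plus an optional rigid ligand
drift along the pocket opening to emulate unbinding.

What this emulates well: the geometry and bookkeeping of the real pipeline —
pocket definition, alignment, pose transfer, ensemble statistics, filter
composition. What it does not emulate: real conformational dynamics
(correlated motions, side-chain rearrangement), real chemistry (the force
field is minimal and the ligand has no torsional flexibility), or the score
distributions of production docking engines. Passing tests therefore
demonstrate that the machinery is correct and the statistics behave as
designed — not that any particular real protein is or is not an off-target,
and not that published ensemble free energies (which require nanoseconds of
explicit-solvent MD on real kinase structures) are reproduced here.

# Problem sizes and numerical choices

The test and demonstration sizes are chosen for a single CPU: demo libraries
of 8–30 targets of 40 residues, screen backgrounds of 60–100 decoy
alignments, NDS backgrounds of 25–50 placements, ensembles of 4–20
snapshots, entropy on systems of ≤ 20 atoms. Exact-clique alignment is used
up to 30 correspondence vertices; larger graphs fall back to the greedy
search, which on planted-similarity problems recovers the same answer (the
demo asserts rank 1 through the full pipeline). Degenerate inputs are
handled explicitly: empty sites warn and propagate as unalignable (score 0),
collinear point sets refuse superposition, constant backgrounds refuse
normalization, unminimized coordinates refuse NMA, and insertion codes are
rejected by the PDB reader rather than silently misparsed.

All randomness flows through explicit integer seeds; reruns with the same
configuration are bit-identical, and the pipeline manifest hash-chains each
stage's output so that a change anywhere upstream is visible downstream.

# Known limitations

Distance-only hydrogen bonds; rigid-ligand optimization; a deliberately
simple interaction score; qualitative network semantics; LCPO parameters
calibrated for the synthetic atom classes rather than taken from a chemical
force field; no mmCIF input; no explicit-solvent energetics. Each is either
out of scope by design or a consequence of keeping every stage verifiable
against an independent oracle at desk scale.
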