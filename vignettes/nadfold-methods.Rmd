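---
title: "Conformational analysis of NAD(H) and pyridone adenine dinucleotides: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nadfold methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Nicotinamide adenine dinucleotide (NAD⁺) and its reduced form NADH are
flexible molecules: the two aromatic bases at either end of the
pyrophosphate linker can stack against each other (folded), sit at an
intermediate separation (semi-extended), or stretch apart as they do when
bound in Rossmann-fold enzyme sites (extended). The pyridone adenine
dinucleotides (2-, 4-, and 6-ox-NAD) are redox-inactive derivatives with a
carbonyl at ring position C2, C4, or C6 of the nicotinamide; they
accumulate under cellular oxidative stress and are candidate inhibitors of
NAD(H)-dependent enzymes, which makes their conformational preferences —
how readily they fold, which glycosidic rotamers they adopt — directly
relevant to which active sites could accommodate them.

`nadfold` implements the full conformational-analysis pipeline for these
five species: all-atom topologies and idealized conformers, per-conformer
geometric descriptors, categorical state assignment, replicate-ensemble
statistics, and mining of protein-bound NAD(H) ligand instances from
structure files. A seeded synthetic-conformer generator stands in for a
molecular-dynamics engine so that every downstream stage runs in seconds
to minutes on one CPU.

## Molecular model

Each species is described by an explicit atom table and covalent bond
graph. The adenosine half (adenine + ribose + phosphate), the
pyrophosphate bridge, and the nicotinamide riboside follow the naming
convention of the wwPDB chemical components NAD and NAI, written with
primes and an A/N suffix (`O4'N` is the nicotinamide-ribose ring oxygen);
`atom_name_map()` translates bijectively to component-dictionary names
(suffix B = adenosine ribose, D = nicotinamide ribose), which is how mined
ligand instances are matched to the analysis names. The pyridone carbonyl
oxygens are named `O2X`/`O4X`/`O6X` because the obvious names collide with
the phosphate oxygens `O1N`/`O2N`.

Protonation is fixed by pH-7 chemistry and by the species' formal states:
the pyrophosphate is fully deprotonated (net −2); NAD⁺ has the aromatic
pyridinium ring (no N1 hydrogen, one H at C4); NADH has the 1,4-dihydro
ring with two hydrogens at C4; each ox species replaces the ring hydrogen
at the oxidized carbon with a carbonyl oxygen, and its ring nitrogen —
substituted by the ribose — carries no hydrogen. This yields 70 atoms for
NAD⁺ and all three ox-NADs and 71 for NADH, which the tests pin exactly.
No alternative tautomer consistent with an N-substituted pyridone
reproduces those counts, so the protonation model is not ambiguous at
this resolution.

## Geometric descriptors

Per conformer the pipeline computes:

* **Inter-base centroid distance d** — distance between the unweighted
  centroid of the 6-atom nicotinamide/pyridone ring and that of all 9
  heavy atoms of the fused purine. The 9-atom purine centroid is the
  common convention for "the adenine ring" when no atom list is given.
* **Inter-base plane angle** — the nicotinamide normal is
  (N1→C2) × (N1→C6), the adenine normal (C5→C4) × (C5→C6); both are
  normalized to unit length before the arccosine of their dot product
  (an arccosine of an un-normalized dot product is undefined behavior),
  and the argument is clamped to [−1, 1] to absorb floating-point drift.
  0° and 180° are parallel stacking.
* **Named torsions** — amide θ (C4N-C3N-C7N-N7N), sugar ν₂
  (C1'-C2'-C3'-C4' of the nicotinamide ribose), glycosidic χ_N
  (O4'N-C1'N-N1N-C2N) and χ_A (C4A-N9A-C1'A-O4'A). Torsions follow the
  IUPAC sign convention (cis = 0°); the implementation is checked against
  an independent projection-formula oracle at 10⁻⁹ degrees on random
  quadruples.
* **Radius of gyration** — mass-weighted, about the center of mass.
* **H-bond group distances** — the four intramolecular donor/acceptor
  groups used for fold tracking, [O3'N–O2'A], [O3'A–O1N],
  [O3'A/O2'A–O4'N], [O3'N/O2'N–O4'A]; a two-pair group enters as the
  minimum of its member distances, so the ≤ 3.3 Å criterion is an OR over
  the pairs and a frame can never count twice in one bin.
* **Fold-event distance** — O4'N–C4A, whose ≤ 4.0 Å criterion (inclusive)
  marks the most common folded form.
* **Superposed RMSD** — heavy atoms by default, after least-squares
  rigid-body (Kabsch) superposition; hydrogens are excluded because their
  positions are placement artifacts, and superposition is the default in
  standard trajectory-analysis libraries. Whether a published RMSD was
  superposition-corrected is not always stated, so
  `rmsd_superposed(..., superpose = FALSE)` exposes the raw variant
  rather than guessing intent.

## Conformational states and window defaults

The underlying distributions are continuous; the package turns them into
reproducible categorical tallies with configurable windows whose defaults
sit midway between the reported population centers:

| state axis | default windows |
|---|---|
| foldedness (d) | folded [0, 6) Å; semi-extended [8, 10] Å; extended [12, 15] Å; else intermediate |
| glycosidic χ | anti [90°, 180°] ∪ (−180°, −90°]; syn [−45°, 90°); else other |
| χ sub-flags | high-anti −60° ± 15°; high-syn +110° ± 15° |
| pucker (ν₂) | C2'-endo ≤ −10°; C3'-endo ≥ +10°; flat otherwise |
| amide (θ) | near-0 ≤ 22.5°; near-180 ≥ 157.5°; offset ± in (22.5°, 90°]; else other |

High-anti and high-syn are sub-flags rather than exclusive states: the
high-syn region plausibly represents a transition between the two main
rotamers, and flagging preserves the primary syn/anti tally. The same χ
windows are applied to the adenosine base, for which no separate boundary
is quantified in the literature this models; that reuse is a package
default, not an assertion about the source analyses. The folded window is
half-open at 6 Å and the others closed, matching how the ranges are
stated. Every window is echoed verbatim into each report header together
with a configuration hash, so a tally can always be traced to its
boundaries.

## The synthetic-conformer generator

The generator emulates the *geometry* of solution ensembles, not their
physics. A template conformer is built for each species from idealized
internal coordinates by sequential bond-length / bond-angle / torsion
placement (a natural-extension-of-reference-frame construction). Aromatic
rings are ideal planar polygons; riboses are built from pseudorotation
phases (C3'-endo P = 18°, C2'-endo P = 162°, flat P = 90°, amplitude
38°), with the furanose ring-closure bond implied by the endocyclic
torsions — it closes to within ≈ 0.07 Å of an ideal bond, which is
immaterial for torsion and distance analysis. Absolute stereochemistry
was verified against an independently embedded β-D-adenosine model
(same chirality determinant at the anomeric carbon), and base/C5' sit on
the same ribose face with the hydroxyls opposite, as in β-D-ribose.

All conformational freedom lives in named torsions: χ_N, χ_A, θ, the two
pseudorotation phases, and eight pyrophosphate backbone torsions. Per
frame the generator:

1. draws a foldedness mode from the mixture weights,
2. draws χ_N syn or anti (truncated normals around +20° and −160°, so the
   drawn label always equals the measured class), χ_A anti, θ from the
   amide-mode weights (centers 0°, 180°, ±45°), and a pucker class,
3. rejection-samples the eight backbone torsions (uniform proposals,
   capped at 10 000 per frame) until d lands in the drawn mode's window
   (folded [3.2, 6) Å — 3.2 Å is about the closest approach such
   ensembles reach — semi-extended [8, 10) Å, extended [12, 15) Å).

Uniform-proposal acceptance rates are 14–20% per window, so sampling is
fast without inverse kinematics. Steric overlap is **not** rejected:
frames are geometric, and a small fraction of folded frames would clash
sterically in a physical model. Consequently, passing parameter-recovery
tests shows that the measurement and classification machinery is
faithful; it says nothing about force fields, solvent, ion association,
or kinetics, and the synthetic time axis (1 ps per frame, hundreds of
frames per replicate) is vastly shorter than the 10 × 100 ns regime the
generator's replicate structure mirrors. Time-based rules (the > 5 ns
cluster spacing) therefore select very few frames on desk-scale
ensembles — expected, not a defect.

Per-species default compositions (mixture weights, syn fraction, pucker
and amide fractions) qualitatively mirror the reported preferences of the
five species — NADH folds more than NAD⁺, 2-/4-ox-NAD fold most while
6-ox-NAD is predominantly extended and syn-rich, 2-ox-NAD avoids syn and
θ = 0 — and are stated once in `species_ensemble_defaults()`; recovery
tests always pass explicit compositions, so the defaults are never tuned
against test outcomes.

## Ensemble statistics

Replicates are concatenated into one time-contiguous trajectory (frame i
at time i × time-per-frame; replicate boundaries kept as metadata).
Histograms are computed per replicate and summarized as per-bin mean and
sample SD across replicates (default 0.5 Å bins over [0, 20] Å — the
granularity such distributions are usually displayed at; configurable).
Representative frames: folded representatives are the frames of the most
prevalent H-bond bin (ties break to the first bin); for each folded frame
the trajectory is scanned backwards — never across a replicate boundary —
for the first frame within ±0.5 Å of the class's histogram peak (argmax
of the mean histogram inside the class window; ties to the
lower-distance bin). RMSD clusters take all frames within 1.0 Å of a
reference and select greedily, earliest first, enforcing pairwise time
separation > 5 ns, stopping at 10 — greedy-earliest is a deterministic
tie-break the source procedure leaves unstated.

## Mining protein-bound NAD(H)

Entries are kept iff X-ray, resolution ≤ 2.9 Å (inclusive), not
C-alpha-only, with ≥ 1 noncovalent NAD/NAI instance; every rejection
carries a reason code, and missing metadata routes to the rejects table
rather than erroring. Covalency is belt-and-braces: a declared covalent
link in the connectivity records, or any ligand–polymer heavy-atom
distance < 1.8 Å. C-alpha-only means > 95% of polymer residues
represented solely by CA. Alternate locations resolve to the
highest-occupancy conformer (ties alphabetically). Instances missing
atoms are flagged per metric, never dropped wholesale. The same geometry
kernels compute the mined metrics — a test pins `mine_metrics` to
`compute_metrics` on identical coordinates, so there is no duplicate
math. Unit tests and the bundled analyses use generated fixture entries
(minimal mmCIF with a poly-alanine stub and template-derived ligand
conformers, labelled synthetic); `fetch_pdb_entries()` isolates live
archive access behind a thin download layer that the test-suite never
touches.

## Problem sizes and numerical choices

The bundled analyses use 5 replicates × 200 frames per species, and the
composition-recovery analysis 10 × 1000 frames — sizes chosen so the full
workflow reruns in a few minutes on one CPU while leaving binomial error
bars (3σ at n = 10 000 is about ±1.2 percentage points on a 20%
fraction) small enough to detect real defects. Dihedral degeneracy
(collinear triples) raises errors rather than returning NaN; angles are
wrapped into (−180°, 180°]; PDB coordinates round-trip at the format's
10⁻³ Å precision; all randomness flows from a single mandatory seed, and
rerunning any stage with the same configuration is byte-identical.

## Limitations

* The generator produces geometry, not thermodynamics: mode weights are
  inputs, never predictions, and no claim about real solution populations
  follows from synthetic runs.
* Idealized bond lengths/angles differ from force-field equilibrium
  values at the few-hundredths-of-an-Ångström level; only torsional
  degrees of freedom are meaningful.
* The mmCIF reader covers the categories the fixtures emit; arbitrary
  archive files with exotic STAR constructs may need pre-conversion to
  PDB format, for which the multi-model reader is the fallback.
* The time axis of synthetic ensembles is nominal; time-based selection
  rules are exercised, but their outputs on desk-scale runs are sparse.
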