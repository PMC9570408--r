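Package: nadfold
Title: Conformational Analysis of NAD(H) and Pyridone Adenine Dinucleotides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric and statistical analysis of the conformational
    landscape of nicotinamide adenine dinucleotide (NAD+ and NADH) and the
    three pyridone adenine dinucleotides (2-, 4-, and 6-ox-NAD). Builds
    all-atom topologies and idealized conformers for the five dinucleotide
    species, computes per-conformer descriptors (inter-base centroid
    distance, ring-plane normal angle, glycosidic and amide dihedrals,
    sugar pucker, radius of gyration, superposed RMSD), classifies
    conformational states (folded/semi-extended/extended, syn/anti,
    C2'-endo/C3'-endo), summarises multi-replicate conformer ensembles
    (replicate-averaged histograms, intramolecular hydrogen-bond fold
    tallies, folded-event detection, representative-frame and RMSD-cluster
    selection), and mines structure files for protein-bound NAD(H)
    ligand conformations. A seeded synthetic-conformer generator emulates
    solution ensembles with a trimodal inter-base distance distribution so
    the whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, bio3d, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
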