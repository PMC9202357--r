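# cyclopep

Cyclic peptides — head-to-tail (backbone) macrocycles and disulfide-bridged
rings of roughly 6–14 residues — are a growing therapeutic class, but their
flexibility and non-standard topology make them awkward for standard
protein–peptide docking pipelines.  A practical route is to dock an
*ensemble* of pre-cyclized conformers rather than a single structure, with
the binding site encoded as ambiguous distance restraints.  `cyclopep`
implements the desk-side half of that workflow for structural biologists and
docking practitioners:

* **Building** — all-atom linear peptides from sequence in two extended
  starting states (β-sheet: φ, ψ = −140°, 135°; polyproline-II: −78°, 149°),
  with charged termini (NH₃⁺ / COO⁻) or ACE/NME caps and pH-7 protonation.
* **Cyclization** — restrained simulated annealing in two steps:
  step 2 pulls the bond-forming atoms together under flat-bottomed distance
  restraints (C–N 1.3 Å and O–N 2.3 Å for head-to-tail; Cα–Cα 4 Å,
  Cβ–Cβ 3.5 Å, Sγ–Sγ 2 Å for disulfides; all ±0.1 Å), and step 3 forms the
  covalent bond — provided N–C ≤ 3.5 Å or Sγ–Sγ ≤ 4 Å — and relaxes the
  closed ring, unrestrained, in its final phase.  Sampling defaults are
  400 models per stage with the four semiflexible annealing phases run at
  4× their base step counts (2000/2000/4000/4000).
* **Clustering** — greedy (Daura-style) pairwise backbone-RMSD clustering at
  2.5 Å; the center of each of the 10 most populated clusters becomes an
  ensemble representative, and repeating step 3 with *k* seeds yields an
  ensemble of up to 10·*k* conformers.
* **Docking preparation** — receptor cleanup (chain merging, HETATM removal,
  `reres`/`shiftres` renumbering), multibody restraints across chain breaks,
  ambiguous interaction restraints (active receptor interface at a 5 Å
  cutoff, fully passive peptide; effective distance `(Σ r⁻⁶)^(−1/6)`),
  CNS-dialect `.tbl` serialization, and the nine benchmark protocol
  configurations (ensemble sizes 5–60; extra flexibility and explicit
  solvent-shell switches, including the length-adaptive variant that turns
  both on only for peptides longer than 10 residues).
* **Assessment** — CAPRI-style quality of docked models against a reference
  complex: fraction of native contacts
  `fnat = |native contacts reproduced| / |native contacts|` with a 5 Å
  heavy-atom contact cutoff (above 0.2 acceptable, above 0.5 medium, above
  0.8 high), interface RMSD over the 10 Å reference interface (below 2.0 /
  1.0 / 0.5 Å, reported separately), and single-structure (top
  N ∈ {1, 5, 10, 20, 50, 100, 200}) and cluster (best N ∈ {1..4} clusters,
  top 4 members each) success rates.

The annealing engine itself is a compact molecular-mechanics surrogate
(template bond/angle/improper terms, trans-ω torsions, purely repulsive
capped r⁻¹² non-bonded term, optional distance-dependent-dielectric
Coulomb) implemented in C++ — enough physics to preserve covalent geometry
and Cα chirality while the restraints drive macrocycle closure.  It is not
a docking engine: `cyclopep` generates docking inputs and evaluates docking
outputs.

## Worked example

Cyclizing a glycine hexapeptide head-to-tail (reduced sampling for speed):

```r
library(cyclopep)
spec <- peptideSpec("GGGGGG", cyclization = "backbone")
conf <- buildLinearPeptide(spec, state = "beta")
endToEndDistance(conf, "backbone")
#> [1] 19.82

writeTbl(cyclizationRestraints(spec))
#> assign (resid 6 and name C) (resid 1 and name N) 1.300 0.100 0.100
#> assign (resid 6 and name O) (resid 1 and name N) 2.300 0.100 0.100

ens <- generateEnsemble(spec, n_seeds = 1, seed = 7, n_models = 20)
sapply(ens$members, endToEndDistance, mode = "backbone")
#> [1] 1.329
restraintDistances(ens$members[[1]], cyclizationRestraints(spec))
#>     d dminus dplus measured
#> 1 1.3    0.1   0.1    1.329
#> 2 2.3    0.1   0.1    2.249
```

The 19.8 Å gap between the termini of the extended build closes to a
1.329 Å amide bond; both cyclization restraints end inside their bounds.
Model quality metrics work the same way on toy complexes with planted
contacts:

```r
toy <- makeToyComplex(seed = 1, n_native_contacts = 4, break_counts = 0:2)
f <- sapply(toy$models, fnat, reference = toy$reference)
f
#> [1] 1.00 0.75 0.50
capriClassify(f)
#> [1] high       medium     acceptable
```

Breaking 0, 1 and 2 of the 4 planted contacts yields fnat 1.0, 0.75 and
0.5 — a high-, a medium- and an acceptable-quality model under the peptide
CAPRI thresholds.

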