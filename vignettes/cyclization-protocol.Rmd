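---
title: "Macrocycle closure by restrained annealing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macrocycle closure by restrained annealing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclopep)
```

# The problem and the procedure

Cyclic peptides bind their receptors through conformations that a single
modeled structure rarely captures.  `cyclopep` therefore produces an
*ensemble* of cyclized conformers and the restraint/configuration files an
information-driven docking engine needs, and scores docked models
afterwards.  The pipeline is:

1. **Build** the linear peptide twice, in a β-sheet-like and a
   polyproline-II-like extended state, all-atom, from internal-coordinate
   templates.
2. **Reduce the gap** (step 2): Langevin simulated annealing of the fully
   flexible peptide under flat-bottomed distance restraints between the
   bond-forming atoms, electrostatics off, four cooling phases, followed by
   a restrained minimization.  Each of the (by default) 400 models starts
   from one of the two builds with freshly randomized velocities.
3. **Close the cycle** (step 3): cluster the step-2 models (2.5 Å backbone
   RMSD), take the centers of the 10 most populated clusters, and for each
   center whose bond-forming atoms satisfy the closure criteria — N–C
   within 3.5 Å head-to-tail, Sγ–Sγ within 4 Å for a disulfide — add the
   covalent bond(s) to the topology and anneal again, restrained in the
   cooling phases and *unrestrained* in a final relaxation run with doubled
   iterations.  Repeating step 3 with k different seeds and keeping up to
   10 cluster centers per run yields an ensemble of at most 10·k members.

Steps 2 and 3 are the package's own single-molecule annealing engine; the
receptor-side preparation, restraint generation, protocol configuration and
CAPRI-style assessment are deterministic bookkeeping around it.

# The energy surrogate

The engine does not reimplement a biomolecular force field.  It uses a
deliberately minimal surrogate whose only job is to keep covalent geometry,
planarity and chirality intact while the restraints do the real work:

* **Bonds and angles**: harmonic, with equilibrium values *measured from
  the template-built conformation*, which is strain-free by construction.
  This avoids a large parameter table and guarantees that annealing pulls
  geometry back toward the build-time ideal.  Bonds created by cycle
  closure instead carry canonical equilibria (C–N 1.329 Å, S–S 2.04 Å, and
  the amide-junction angles), registered as explicit overrides.
* **Impropers**: one harmonic (wrapped) dihedral per trigonal or chiral
  center — three-neighbor atoms get their built value (planarity), atoms
  with three heavy neighbors plus hydrogens get the built value of the
  heavy-atom triple (Cα chirality, barrier far above thermal energy).
* **ω torsions**: each inter-residue C–N bond, including a closure bond,
  carries a harmonic trans-ω term.
* **Non-bonded**: purely repulsive `eps · ((σᵢ+σⱼ)/r)¹² − eps`, active only
  below contact distance and linearly capped at short range so forces stay
  finite; 1-2, 1-3 and 1-4 pairs are excluded.
* **Electrostatics** (optional): Coulomb with a distance-dependent
  dielectric, `E = C qᵢqⱼ/r²`, with unit formal charges spread over
  terminal atoms of charged groups.  Per the protocol it is *off* during
  the annealing phases — with it on, charged side chains tend to collapse
  into the ring center — and on only in the final minimization, as a mild
  solvent-screening surrogate.
* **Restraints**: flat-bottom harmonic with a linear asymptote beyond a
  0.5 Å switch offset (soft-square form).  Ambiguous restraints are
  evaluated on the effective distance `(Σ r⁻⁶)^(−1/6)`, a soft minimum
  that is always ≤ the closest pairwise distance.

All gradients are analytic (verified against central finite differences in
the test suite).  Energies are in arbitrary thermal units; `kB = 0.001`
converts schedule temperatures into them.

## Integrator and schedule

Temperatures cool geometrically from 1000 to 50 thermal units across the
four phases — the staged semiflexible-refinement analogy, with the peptide
fully flexible throughout, as the cyclization protocol prescribes.  The
step counts are the stage defaults (500, 500, 1000, 1000) multiplied by 4,
i.e. 2000/2000/4000/4000.  The integrator is Langevin in Cartesian space
(dt = 0.004, γ = 2 in the surrogate's units) with a per-component velocity
guard for stability on steep contacts; frozen atoms (when a schedule
freezes backbone or side chains) get zero force and velocity.  The final
phase is a steepest-descent minimization with backtracking line search, so
the energy after the final relaxation is never above the energy before it.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| β state (φ, ψ) | (−140°, 135°) | extended sheet-like start |
| PPII state (φ, ψ) | (−78°, 149°) | polyproline-II start |
| head-to-tail restraints | C–N 1.3 Å, O–N 2.3 Å (±0.1) | mean amide-bond geometry; O–N shapes the O–C–N angle |
| disulfide restraints | Cα–Cα 4, Cβ–Cβ 3.5, Sγ–Sγ 2 Å (±0.1) | mean distances in disulfide-cyclized peptides |
| combined cyclization | C–N, O–N, Cα–Cα, Sγ–Sγ | the Cβ–Cβ restraint is omitted |
| closure criteria | N–C ≤ 3.5 Å; Sγ–Sγ ≤ 4 Å | bond is only formed below these |
| models per stage | 400 | step-2 and step-3 sampling |
| clustering cutoff | 2.5 Å backbone RMSD | conformer clustering |
| representatives | 10 per run | centers of the most populated clusters |
| AIR | target 2.0, −2.0/+0.0 Å | active receptor residue vs. all passive peptide residues |
| interface cutoff | 5 Å heavy-atom | active-residue definition and fnat contacts |
| i-rmsd interface | 10 Å | reference-interface residues, backbone atoms |
| docking sampling | 5000/400/400, it1 steps ×4 | base configuration of all nine protocols |
| docked-model clustering | interface-ligand RMSD, 5 Å | configuration field only (docking itself is out of scope) |

# Design choices where the design was open

* **Backbone dihedrals of the two starting states** are not canonical
  constants anywhere; the textbook values above are used and are
  configurable per call (`dihedrals =`).
* **Proline** keeps φ ≈ −78° regardless of the requested state: its
  pyrrolidine ring is rigid relative to the N–Cα–C frame, and forcing
  φ = −140° drives the ring through the preceding carbonyl.  The builder's
  φ/ψ contract therefore exempts proline.
* **Protonation at pH 7**: Asp/Glu deprotonated, Lys/Arg protonated,
  His neutral with the proton on Nε2, Cys thiols protonated *unless* the
  residue is named in the declared disulfide pair (those Sγ stay bare, ready
  to bond).
* **ACE/NME caps are built directly** from templates rather than by adding
  and mutating glycines; the resulting atom records are the same and the
  detour only existed because of external tooling.
* **Side-chain rotamers**: extended (χ = 180°, branches at ±60°) at build
  time — annealing handles packing, so a rotamer library would add nothing.
* **Hydrogens are emitted** by geometric valence completion; whether a
  builder should emit them was open, and downstream topology is simpler
  with them present.
* **AIR numeric convention** (2.0 Å target, 2.0 lower / 0.0 upper
  correction) follows the established active/passive-to-ambiguous
  generators, which never print these numbers in prose.
* **Chain-break detection** for body restraints: C(i)–N(i+1) > 2.5 Å or a
  residue-numbering gap.  Two restraints per body pair (first-to-last and
  last-to-first Cα), targets fixed at the measured distances with zero
  corrections, so all bodies form one rigid constellation.
* **Clustering algorithm**: greedy neighbor-count (Daura) clustering, the
  algorithm behind the cited RMSD-clustering practice; backbone-only RMSD
  by default (heavy-atom selection was the open alternative).  All
  tie-breaks are by lower model id: neighbor-count ties, center ties, and
  equal-population rank ties, making clustering invariant to input order.
* **Cluster center** = member with minimal mean RMSD to its co-members.
* **Step-2 clustering with fewer than 10 clusters** contributes the
  available centers, mirroring the documented step-3 rule.
* **Step 3 re-randomizes velocities only**, not conformations; the
  representatives are the point of step 2 and scrambling them would waste
  it.
* **Ranking ties** in assessment are broken by model id (stable order);
  determinism is worth more than any particular tie philosophy.
* **i-rmsd interface cutoff**: never stated alongside the metric; 10 Å
  backbone, the CAPRI convention, is used.  This matters when comparing
  absolute i-rmsd values across tools.
* **Model score** inside the engine is internal plus restraint energy; a
  full docking score function is out of scope.
* **Explicit-solvent refinement** is approximated by the final minimization
  with the distance-dependent dielectric — a declared surrogate, not a
  solvent model.

# What the synthetic fixtures emulate — and what they do not

`makeToyComplex()` builds single-atom-per-residue receptor/peptide pairs
with exactly *n* planted contacts at 4.5 Å and perturbed copies whose
surviving-contact count is known, so fnat, interface extraction and the
success machinery can be verified against construction bookkeeping.
`makeQualityTable()` plants (rank, class) events in otherwise-incorrect
ranked model lists, making success rates computable by hand.

These fixtures are oracles for the *bookkeeping*, not for docking physics:
they contain no side-chain packing, no competing binding modes, no scoring
noise.  A passing suite demonstrates that the metrics, thresholds,
clustering and success-rate logic are implemented exactly; it says nothing
about how often real docked cyclic peptides land near-native — that depends
on the docking engine this package feeds.

Similarly, the cyclization tests run the real annealing engine but at
reduced sampling: the convergence property (at least one step-3
representative with every restrained distance inside its bounds) is checked
for a glycine hexapeptide at 40 models per stage with fixed seeds, and unit
tests use 2–8 models.  The protocol default of 400 models per stage is the
production setting; reduced sampling checks the machinery, not the
statistics of hard sequences.

# Numerical notes and degenerate inputs

* The builder is deterministic (bit-identical rebuilds); annealing is
  deterministic in (spec, seed) through a counter-based per-model seed
  derivation, so runs are reproducible even if models are farmed out.
* A zero-step schedule is a valid degenerate input: models pass through
  unchanged (used as a test identity).
* Restraint satisfaction checks use a 1e-9 tolerance on the bounds;
  dihedral terms wrap into (−180°, 180°]; near-linear angles are clamped
  before `acos`.
* Empty selections, empty interfaces, capped termini asked to form
  head-to-tail bonds, references without contacts, cutoffs ≤ 0 and
  structures with fewer than two residues are all explicit rejections, not
  silent empties — except the empty active-residue interface, which warns
  and returns an empty list (a non-binding reference is a data property,
  not a usage error).
* PDB output is fixed-format; files written by the package re-read and
  re-write byte-identically, and altloc duplicates resolve to the highest
  occupancy with a warning.

# Known limitations

* The surrogate force field has no attractive dispersion, no hydrogen-bond
  term and no solvent; relaxed rings are geometrically sound but their
  relative conformer energies are only indicative.  Ensemble diversity for
  very smooth sequences (poly-Gly) can collapse to a single cluster.
* D-amino acids, non-standard residues beyond the ACE/NME caps, and
  multiple disulfides per peptide are unsupported.
* The docking stages themselves (rigid-body search, scoring, explicit
  solvent refinement) are out of scope: `protocolConfig()` and
  `writeRunParams()` emit the configuration deltas for an external engine,
  and only those deltas — unlisted engine parameters follow that engine's
  defaults.
* Residue correspondence in assessment is by residue number after receptor
  preparation; there is no sequence-alignment fallback.
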