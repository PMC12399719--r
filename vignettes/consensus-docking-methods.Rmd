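---
title: "Methods: consensus docking, pose filtering and trajectory occupancy"
author: "consdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus docking, pose filtering and trajectory occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`consdock` implements the bespoke computational stages of a hierarchical,
consensus-docking virtual screen against ALDH1A3, the retinaldehyde
dehydrogenase whose catalytic cysteines (C313/C314) anchor the binding mode
of retinoic acid and of the carboxylate/isoindoline-1,3-dione chemotypes the
screen selects for.  The package deliberately does *not* dock or simulate:
docking engines, conformer generators and MD packages are external, and
their outputs (poses, trajectories) are this package's inputs.  A
first-class synthetic-data module generates inputs with the same
statistical structure, so every stage is testable end to end without any
commercial tool.

The pipeline stages are:

1. **Prescreen** — a substructure requirement (by default one carboxylic
   acid, SMARTS `C(=O)[O;H1,-]`), a Gaussian shape-overlap Tanimoto against
   a query molecule (default cutoff 0.65), and rule-based drug-likeness
   windows (Lipinski: MW <= 500, logP <= 5, donors <= 5, acceptors <= 10).
2. **Hierarchical H-bond filter** — after each docking stage, a compound
   survives iff its top-ranked pose forms at least one geometric hydrogen
   bond with a required residue (default C313/C314).  Stage bookkeeping
   reports the residual percentage against the *first* stage's input.
3. **Consensus docking** — for each surviving ligand, the pairwise
   symmetry-aware RMSD matrix over one top pose per docking program,
   complete-linkage clustering at 2.0 Å, and a consensus level defined as
   the number of distinct programs represented in the largest cluster.
   Ligands with level >= 9 (of 12) are selected.
4. **Trajectory analysis** — per-frame interaction occupancy, protein-CA
   and ligand-heavy-atom RMSD series versus the first frame, windowed
   re-analysis, and stride-based clustering of trajectory frames with a
   representative (medoid-like) frame from the most populated cluster.
5. **End-state energy combination** — `delta_g_combine()` applies
   dG_bind = E_complex − E_ligand − E_receptor to externally computed
   component energies; no MM-GBSA engine is included.

# Geometric criteria and conventions

**Hydrogen bonds.** Donor–acceptor heavy-atom distance <= 3.5 Å
(inclusive) *and* D–H...A angle measured at the hydrogen > 120°
(exclusive), the boundary conventions chosen to mirror the stated "<= 3.5"
and "> 120" criteria; both are `hbond_criteria()` parameters.  Donors are
N/O/S atoms carrying at least one explicit hydrogen — hydrogens are never
added implicitly, so structures must arrive protonated; thiol sulfur both
donates (when protonated) and accepts, which is what lets the catalytic
cysteines anchor the screen.  An N/O/S atom without hydrogens is simply a
non-donor (a carbonyl oxygen); a structure containing *no* hydrogens at all
triggers one logged message per side, and there is no distance-only
fallback.  Protein hydrogen attachment is resolved by a 1.45 Å
intra-residue distance criterion (covering O–H ~0.97, N–H ~1.01 and
S–H ~1.34 Å without reaching non-bonded contacts); ligand attachment uses
the bond table.

**Other contacts.** π-stacking: ring-centroid distance <= 5.5 Å with the
acute inter-normal angle <= 30° (face-to-face) or >= 60° (edge-to-face);
protein rings are perceived by atom name for PHE/TYR/HIS/TRP, ligand rings
from aromatic bond flags.  Hydrophobic: ligand-carbon to side-chain-carbon
contacts of apolar residues (A, V, L, I, P, F, M, W) within 4.5 Å,
aggregated per residue.  Halogen: C–X...acceptor with X...A <= 3.6 Å and
the angle at the halogen >= 140°.  None of these three thresholds is
prescribed by the screening protocol itself; the defaults are conventional
values and all are arguments.

**Aromaticity** is trusted from input flags (SDF bond type 4, MOL2 `ar`)
and never re-perceived, which keeps SDF/MOL2 parity trivially exact.

# Symmetry-aware pose RMSD

Docking-pose RMSD is computed over heavy atoms only, in place (no
superposition) by default, because redocking validation and consensus
clustering compare poses that share the receptor frame; `superpose = TRUE`
applies an optimal Kabsch fit per symmetry image when a frame-independent
comparison is wanted.  Chemical symmetry (carboxylate oxygens, phenyl
flips) is handled by minimizing over automorphisms of the heavy-atom
multigraph, with element labels on atoms and bond orders (aromatic
distinct) on edges; automorphisms are found by backtracking over an
iterated neighbourhood-colour refinement, with a configurable cap
(default 10,000) against pathological inputs.  Poses being compared must
carry the same atom ordering; differing heavy-atom graphs are an error.

The redocking acceptance test is `RMSD <= 3.0 Å`, boundary inclusive.

# Complete-linkage consensus clustering

The clustering is agglomerative max-linkage, stopping when the smallest
complete-linkage distance between clusters exceeds the cutoff (2.0 Å
default).  Cutting at merge height <= cutoff guarantees the property the
selection relies on: every within-cluster pairwise RMSD is at most the
cutoff.  All tie-breaks are deterministic — merge ties by smallest member
index, cluster numbering by decreasing size then smallest member, and
largest-cluster ties (for the consensus level) by more distinct programs,
then smallest member index — so results are invariant to pose reordering
and there is no randomness anywhere in the module.  The matrix is always
the full symmetric n x n over all poses of a ligand.

The consensus level counts distinct *programs*, not poses, in the winning
cluster (a duplicate pose from one program counts once); the raw largest
cluster size is reported alongside.  Selection keeps ligands with level at
least `min_level` (default 9) and emits a level histogram.

# Gaussian shape overlap

Each heavy atom is a spherical Gaussian `p * exp(-alpha r^2)` with uniform
radius 1.70 Å and amplitude `p = 2 * sqrt(2)`; `alpha` is fixed so a single
Gaussian integrates to the hard-sphere volume of that radius, and this
amplitude makes an isolated atom's self-overlap equal that volume
(20.58 Å^3).  Molecular overlap is the integral of the product of the two
total densities — exact, pairwise, first order (no multi-body
corrections) — and the Tanimoto is `O_AB / (O_AA + O_BB − O_AB)`, which
Cauchy–Schwarz keeps in [0, 1].  A uniform radius was chosen over element
radii because the screening protocol prescribes none and a uniform sphere
keeps the quadrature oracle simple; the radius is an argument.

Alignment is deliberately cheap: centre both molecules on their heavy-atom
centroids, rotate into principal axes (deterministic sign convention), try
the four proper axis flips, keep the best.  There is no gradient
refinement, so near-degenerate inertia tensors (an ideal benzene) can
align suboptimally; the toys used in tests have distinct principal
moments.  Conformer enumeration is the caller's job — the screen that
motivated this package used 500 externally generated conformers per
ligand, and a multi-conformer SDF can be fed record by record.  The 0.65
cutoff is configuration, not a constant.

# Trajectory analyses

Every frame is superposed onto frame 1 by a Kabsch fit over protein
α-carbons before anything is measured; the reference is the supplied
trajectory's own first frame (the deviation "from the initial pose"),
overridable with an external reference.  Ligand RMSD uses heavy atoms
only.  Occupancy counts a frame once per interaction key
(kind + residue) regardless of how many atom pairs qualify, matching the
per-residue percentages such analyses report; keys never observed are
omitted.  Windowed reports recompute metrics independently per window, so
the union occupancy is exactly the frame-weighted mean of window
occupancies.

Trajectory clustering subsamples every `stride`-th frame (stride is in
*frames*, default 10 — the analysed campaign's recording interval of
200 ps/frame makes its stated "every 10th" ambiguous between frames and
ns, and frames is the implementable reading; it is configurable), builds
the ligand-heavy-atom RMSD matrix after CA superposition, and reuses the
complete-linkage module.  The RMSD cutoff is a *required* argument: the
external tool the campaign used does not state its value, so no default
fidelity is claimed.  If more than `max_clusters` (default 5) clusters
result, the largest are kept and the rest pooled as unclustered.  The
representative frame minimizes the summed RMSD to its co-members within
the most populated cluster, so it is always a real frame.

# Synthetic data: what it emulates, what it does not

The generators plant ground truth with margins that keep recovery off the
decision boundaries, then let the tests ask for exact recovery:

* `gen_pose_ensemble()` plants `n_consensus` poses as rigid jitters of a
  base pose with maximum heavy-atom displacement `cluster_radius / 2`
  (translation <= r/4 plus a rotation capped to displace <= r/4), so every
  within-cluster pairwise RMSD is at most `cluster_radius` (default 1.0 Å,
  safely under the 2.0 Å cutoff).  Outlier translations have magnitudes
  spaced by `outlier_offset` (default 8 Å) along random directions, which
  bounds outlier–outlier and outlier–cluster RMSDs away from the cutoff by
  construction rather than by luck.
* `gen_receptor_with_pocket()` builds a six-residue chain
  (G311–A312–C313–C314–T315–G316) with a wiggly, non-coplanar CA trace
  (so rigid superposition is fully determined) and thiols pointing into an
  open half-space.  Contact poses place the ligand's first carbonyl oxygen
  at d = 2.8 Å and 160° off the S–H axis — 0.7 Å and 40° inside the
  criteria; non-contact poses put every ligand atom beyond 3.7 Å of every
  polar protein atom.  Labels are therefore exact by construction.
* `gen_trajectory()` plants per-residue H-bond occupancies on
  deterministic, evenly spread frame masks (exactly `round(n * f)` frames)
  or Bernoulli masks, with Gaussian coordinate noise; hydrogens ride with
  their parent heavy atom so bond geometry never breathes across a
  detector criterion, and the planted acceptor position is restored
  exactly on planted frames.  A two-state mode alternates bound and
  displaced ligand positions for clustering tests.

Every generator takes a mandatory seed and uses one seeded stream per
call; identical seeds give byte-identical output.

What the synthetic data does *not* emulate: real docking score
distributions, induced fit, solvent, correlated thermal motion, cluster
shapes other than "tight ball plus remote outliers", and partial or
borderline H-bond geometry.  Passing the recovery suites therefore
demonstrates that the machinery is correct and deterministic, not that the
thresholds are optimal for any particular real screen.

# Numerical choices

* Residual percentages are `100 * n_out / n_initial` rounded to two
  decimals with round-half-even.  Two cells of the published funnel table
  this package's bookkeeping was checked against appear truncated rather
  than rounded (0.91 and 0.22 where the quotients give 0.92 and 0.23); the
  rounding convention is documented here and not bent to match.
* Clustering tolerates distance ties via an explicit 1e-12 comparison
  band; matrices must be symmetric with zero diagonal to 1e-8.
* The SMARTS engine supports the subset the pipeline needs: organic-subset
  and aromatic atoms, brackets with element/aromatic/`Hn`/charge
  primitives, `,`/`;` logic, bond symbols `- = # : ~`, branches and ring
  closures.  `Hn` counts explicit hydrogens.  Patterns outside the subset
  are rejected loudly rather than mis-parsed.
* The crude additive logP in `basic_descriptors()` is a screening-grade
  estimate for the toy library only; real campaigns should supply
  predicted descriptors to `druglike_check()`.
* Problem sizes in the test and acceptance suites — 1000 random matrices
  (n <= 7) against an independent clustering implementation, brute-force
  automorphism enumeration on graphs up to 11 heavy atoms, 0.05 Å grid
  quadrature on 1–6 atom systems, 100 planted ensembles, 500-frame
  occupancy recoveries — were chosen so the whole suite completes in a few
  minutes on one core while still exercising every decision path.

# Known limitations

* Pose comparison requires identical atom ordering between poses; no
  graph-matching is attempted for differently ordered inputs.
* PDB-derived ligands carry no bonds (CONECT is ignored); detectors then
  fall back to distance-based H attachment, and `read_trajectory()`
  accepts a template graph to restore full connectivity.
* Protonation, tautomers and structure preparation are out of scope, as is
  SDF V3000 and mmCIF.
* Water-mediated hydrogen bonds are not modelled (the analysed system
  retains no structural waters at the site).
* The shape aligner's four-flip principal-axes search can miss the global
  optimum for molecules with near-degenerate inertia; a gradient refiner
  was considered and rejected as out of proportion to the filter's role.
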