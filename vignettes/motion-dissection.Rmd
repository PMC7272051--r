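---
title: "Dissecting function-specific collective motions in multi-signaling receptor complexes"
author: "MotionDissect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting function-specific collective motions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Some receptors signal through more than one downstream pathway, and a
ligand variant can silence one pathway while leaving the others intact
(biased signaling).  A structural hypothesis for such behaviour is that
each signaling outcome is driven by a distinct *collective motion* of the
ligand-receptor complex, and that a point mutation can selectively abolish
the motion tied to the lost outcome.  MotionDissect implements a workflow
for testing this hypothesis computationally: compute the low-frequency
normal modes of the wild-type and variant complexes, describe each mode's
motion by an internal-coordinate fingerprint, measure which motions the two
systems share, and — given which outcomes each system supports
experimentally — assign motions to outcomes.  Each motion class is then
dissected with correlation maps, residue interaction networks,
communication paths and interaction inventories.

## The model

### Normal modes from a pluggable Hessian

Collective motions are taken from the mass-weighted eigenproblem
$H v = \lambda M v$.  The Hessian is pluggable; the default is the
anisotropic elastic network model (ANM): every particle pair within a
cutoff $r_c$ (default 10 Å) is joined by a harmonic spring of uniform
stiffness $k$ (default 1) at its reference length, giving off-diagonal
$3\times3$ superblocks $-k\,\hat r \hat r^{\mathsf T}$ and diagonal blocks
that enforce exact translational invariance.  This is a deliberate design
choice, stated loudly: an all-atom force-field Hessian (the kind a
molecular-mechanics package would produce after deep minimisation) is out
of scope here, and every downstream step of the workflow is agnostic to
where the Hessian came from — `computeNormalModes()` accepts any symmetric
matrix.  A connected three-dimensional network has exactly six near-zero
(rigid-body) eigenvalues; these are counted and excluded, and analysed
modes are labelled from 7 upward, the field's convention.  The zero-mode
tolerance is $10^{-8}$ of the largest eigenvalue — far below the lowest
internal mode of any connected network we generate, and far above the
$10^{-13}$-scale numerical zeros of the rigid modes.  Eigenvector signs
are fixed (largest-magnitude component positive) so the decomposition is
bit-reproducible.

By default 20 non-trivial modes are analysed per system; the computed pool
can be raised to 200.  Twenty low modes are where collective,
domain-scale motions live; higher modes are increasingly local and their
fingerprints increasingly noisy.

### Mode trajectories

Each mode is turned into a pseudo-trajectory of 21 frames at equally
spaced mass-weighted RMS (MRMS) displacements in $[-1, +1]$ Å.  With
`relax = FALSE` the frames are exact harmonic displacements (achieved MRMS
equals the target to machine precision, and the trajectory is exactly
antisymmetric about the reference frame).  With `relax = TRUE` each frame
is relaxed under the elastic-network energy plus a harmonic restraint on
the signed MRMS coordinate along the mode
($E + \tfrac{w}{2}(c - c_0)^2$, $w = 50$ by default), starting from the
harmonic displacement.  Relaxation is the step that lets the structure
escape strict harmonicity, and it is what gives the mode-transfer
experiment its teeth: a frame relaxed under the *variant's* network can
drift away from the same frame relaxed under the wild-type network
precisely where their spring topologies differ.  We minimise with
L-BFGS (analytic gradient, projected-gradient tolerance $10^{-5}$, up to
2000 iterations) rather than plain gradient descent: the restrained ENM
energy is smooth and cheap, and a quasi-Newton minimiser reaches the
restrained minimum reliably where a fixed-step descent stalls; each frame
is relaxed independently from its own harmonic start so that the result is
a property of the energy surface, not of a continuation path.
Non-converged frames are flagged per frame, never fatal.

Frame count (21) and the restraint weight are our own operating choices —
they are not prescribed by the underlying method — and both are exposed in
the run configuration.

### Motion fingerprints and the Mantel similarity graph

A motion is fingerprinted as the Cα distance-difference matrix
$\Delta M = M_{+} - M_{\chi}$ between the $+1$ Å frame and the reference.
Internal distances make the fingerprint invariant to rigid-body motion and
comparable across systems with different orientations.  The mirror matrix
$M_{-} - M_{\chi}$ is computed and its correlation with $\Delta M$
reported (for a harmonic mode it is close to $-1$; anharmonicity shows up
as departures from that), but only the plus matrix is kept.

Two fingerprints are compared with a Mantel permutation test: $r$ is the
Pearson correlation of the vectorised upper triangles, and the null
distribution permutes rows and columns of one matrix simultaneously.
Significance is two-sided on $|r|$ because an eigenvector sign flip
negates a fingerprint wholesale.  For matrices of dimension ≤ 7 all $n!$
permutations are enumerated and the p-value is the exact fraction (the
identity is included, so $p \ge 1/n!$); above that, 9999 random
permutations with the standard $+1$ correction so $p$ is never zero.
Modes are connected in the similarity graph when $|r| \ge 0.6$ **and**
$p < 0.001$.  Since a permutation p-value cannot rescue a pair that fails
the $|r|$ screen, the permutation test is run only for pairs at or above
the threshold; the full $r$ matrix is retained and exported either way.
Cross-system pairs are aligned on shared residue keys (or through an
explicit residue mapping), so a substitution site — whose Cα exists in
both systems — stays in the comparison.

We compare *relaxed trajectories*, not raw eigenvectors: direct
eigenvector overlap is deliberately out of scope, because it cannot see
the anharmonic relaxation effects that distinguish the two topologies.

### Classification

Motions are clustered as connected components of the thresholded graph —
the simplest rule that reproduces the visual grouping such similarity
graphs are read by.  A component spanning several systems is a *shared*
motion, tagged with the outcomes all its systems support; a component
confined to one system is *unique* to it, tagged with the outcomes that
distinguish that system from the common set, or `"novel"` when none do.
With a wild type supporting both outcomes and a variant supporting only
one, this reproduces the three-way split: shared motions (the retained
outcome), wild-type-unique motions (the lost outcome) and variant-only
motions (new, function-unassigned).  Classification refuses to run on a
single system; an intra-system redundancy report is produced instead.

### Mode transfer

To ask whether the variant *could* perform a wild-type-unique motion, the
wild-type mode direction is re-indexed onto the variant through the
residue mapping (unmapped positions get zero displacement; at least 90 %
of the acceptor's Cα positions must be mapped), renormalised in the
acceptor's mass metric, and used to generate a relaxed trajectory under
the acceptor's own elastic network.  The resulting fingerprint is compared
by Mantel test against the donor's original; the motion is *preserved*
when the pair passes the same $|r| \ge 0.6$, $p < 0.001$ rule.  A lost
motion means the acceptor's topology reshapes the displacement into a
different pattern of internal-distance changes — the mechanistic signature
of a mutation that abolishes a functional motion.

### Per-class dissection

For each (system, class) group of modes, the group's trajectories are
pooled frame-wise and analysed:

* **DCCM** — $C(i,j) = \langle \Delta r_i \cdot \Delta r_j \rangle /
  (\langle \Delta r_i^2\rangle^{1/2} \langle \Delta r_j^2 \rangle^{1/2})$
  over Cα atoms, displacements about the ensemble mean.  Frames are
  least-squares superposed onto the reference first; this is a no-op for
  harmonic trajectories (modes carry no net rigid motion) and a safeguard
  for relaxed ones.  Atoms with zero fluctuation get `NA` rows rather than
  zeros.  Concatenating frames (rather than averaging per-mode maps) is
  our resolution of a genuinely open choice; each mode contributes equal
  frame counts.
* **Group RMSF** — per-atom root-mean-square deviation from the initial
  structure, averaged over each mode's frames, the atom's three degrees of
  freedom, and the group's modes, then square-rooted.  No superposition by
  default, so the profile is an exact evaluation of its definition.
* **Dynamical network** — nodes are Cα positions; an edge requires
  $|C(i,j)| \ge 0.7$ *and* a Cα–Cα contact within 10 Å in at least 75 % of
  the pooled frames; the weight is $-\log|C|$ (capped just below
  $|C| = 1$ so weights stay positive), making strong correlations short
  distances — path length decreases as correlation increases by
  construction.  Isolated nodes are retained.
* **Communities** — Girvan–Newman divisive clustering on edge betweenness
  (weights as distances).  Strict modularity maximisation tends to
  over-fragment, so among all dendrogram cuts whose modularity is within
  0.05 of the maximum we return the one with the fewest communities, then
  prune communities under 10 nodes (members reported unassigned).
  Modularity is evaluated with $|C|$ strengths.  Inter-community coupling
  is the summed $|C|$ over crossing edges, normalised by the largest such
  sum.
* **Paths** — betweenness centralities, plus the $k = 500$
  lowest-total-weight simple paths between chosen endpoint pairs (Yen-type
  enumeration), sorted by length with lexicographic tie-breaks for
  determinism.  Node degeneracy is the fraction of the ensemble's paths
  through each node (source and sink are by definition 1).  When no
  endpoints are configured, the two highest-betweenness nodes are used.
* **Interactions** — hydrogen bonds (donor–acceptor ≤ 3.0 Å and
  D–H···A within 20° of linear; the angle convention is
  deviation-from-180° at the hydrogen) and salt bridges (anionic
  side-chain O to cationic side-chain N ≤ 3.2 Å), aggregated to exact
  per-frame occupancies.  The high-occupancy screen is 50 %, inclusive.
  Structures without hydrogens (Cα bead models, unprotonated files) fall
  back to distance-only detection, flagged `heavyOnly`.  Cross-system
  diffs report gained / lost / kept residue pairs above the screen.

## The synthetic test system

`generateComplex()` builds coarse-grained multi-chain bead complexes; the
default is a *dimer-of-dimers* (4 chains × 30 beads, helical chains at
~3.8 Å bead spacing, chain axes ~7 Å apart, ±0.3 Å seeded jitter, uniform
100 amu beads) mimicking a 2:2 ligand/receptor stoichiometry, so
chain-block structure in DCCMs and inter-chain community couplings have
meaningful analogues.  `generateVariantPair()` derives a variant that
shares the wild-type *coordinates* but loses a seeded 30 % of the springs
within 8 Å of a designated interface bead (chain B, residue 15), whose
residue name flips ARG→TRP so the mapping flags exactly one mutation.
This is the bead-model caricature of a point mutation that rewires local
contacts without moving the backbone.

`canonicalVariantPair()` freezes this fixture together with the
shared/disrupted/transfer-lost labels observed in the first full run at
the default operating point.  Those labels are regression references — a
property of this fixture under this configuration, not external truth —
and the tests assert them so any future change in numerics is noticed.

What the fixture does *not* emulate: side-chain chemistry (the mutation is
purely topological), solvent, anharmonic force-field effects beyond the
spring network, and realistic mass distributions.  Passing tests therefore
demonstrate that the machinery — modes, fingerprints, Mantel clustering,
classification, transfer, network dissection — behaves correctly and
recovers engineered ground truth; they do not demonstrate that any real
receptor loses a motion.

## Numerical choices and degenerate inputs

* Eigen-decomposition is LAPACK's symmetric solver; determinism comes from
  the sign convention, not from the solver.
* Mantel permutation seeds are derived per pair (`seed + pair index`) so
  results are independent of evaluation order; the pipeline derives stage
  seeds from the single global seed (`+1000` similarity, `+2000`
  transfer), so adding a stage never shifts another's random stream.
* Zero-variance fingerprints (a motion with no internal distance change,
  e.g. a pure rigid-body direction) make $r$ undefined and raise an
  explicit error rather than returning 0.
* $|C| = 1$ in synthetic data is capped at $1 - 10^{-12}$ before
  $-\log$; zero-fluctuation atoms are `NA`, never 0.
* Girvan–Newman ties and equal-length paths are broken lexicographically.
* An edgeless network yields an all-unassigned partition with a warning;
  a disconnected source–sink pair yields an explicit empty path ensemble.
* Overlapping beads, zero-distance particle pairs, disconnected
  perturbations and below-coverage transfers are hard errors.

## Problem sizes used in the shipped analyses

The test suite exercises the full study conditions once: the canonical
120-bead variant pair, 20 modes per system, 21-frame relaxed
trajectories, 9999-permutation Mantel tests, 500-path ensembles.
Oracle-backed unit tests run on 2–25-bead fixtures, ≤ 14-node graphs
(brute-force modularity over all bipartitions) and ≤ 9-node graphs
(exhaustive simple-path enumeration), where independent recomputation is
exact.  The acceptance script re-runs the canonical study end to end and
additionally checks byte-level determinism on a reduced configuration
(6 modes, 7 frames), since determinism is a property of the machinery,
not of the problem size.

## Known limitations

* The default Hessian is a uniform-k Cα/bead network: mode *frequencies*
  are not physical, only the geometry of the low-frequency subspace is
  meaningful, which is all the workflow uses.
* Classification depends on the 0.6/0.001 edge rule; near-threshold pairs
  can flip class between operating points.  The full $r$ and $p$ matrices
  are exported so such cases can be audited.
* The transfer experiment relaxes under the acceptor's ENM only; it
  cannot capture side-chain-level rescue or steric clash, both of which
  need atomistic detail.
* Hydrogen-bond detection on bead models degenerates to a contact
  criterion (flagged); angle-resolved detection needs hydrogens.
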