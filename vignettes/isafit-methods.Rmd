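---
title: "Geometric fitting of ubiquitylated linker histones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric fitting of ubiquitylated linker histones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isafit)
```

# Scope

`isafit` answers a purely geometric question about a two-domain ligand
(a linker-histone globular domain carrying ubiquitin on one of its
lysines, "HUb") and a nucleoprotein receptor (a nucleosome or
chromatosome): after superposing the histone subunit onto the
crystallographic linker-histone position, how severely does the
ubiquitin subunit interpenetrate the receptor? Around that core the
package provides the supporting machinery of the workflow it belongs
to — collective variables for dimensionality reduction, iterative
density-based clustering of 2D projections into structurally
homogeneous conformational states, restart selection for
expansion-scheme sampling, and synthetic generators that emulate each
scenario for testing. MD simulation itself, the sketch-map projection
algorithm, and physics-based rescoring are out of scope; projections
are ingested as plain two-column tables.

# The interpenetration score

## Occupancy grid

Receptor atoms are binned on an axis-aligned grid. The default bin
width is 1 Å (isotropic, configurable); the receptor's bounding box is
padded by one bin on every side so that all corner bins are empty.
Bins are half-open, `[low, high)`: an atom exactly on a boundary goes
to the higher-index bin. Atoms outside a user-supplied box are dropped
with a warning count (never silently).

A plain histogram at fine resolution is mostly zeros: an atom slipped
*between* receptor atoms, or into an interior cavity, would score 0.
The remedy is cumulative: from each of the 8 corners of the box a
cumulative histogram is built in which bin *b* holds the **total atom
count in the axis-aligned sub-box between that corner and b,
inclusive**. We formalize the construction as a 3D
inclusion–exclusion prefix sum (a summed-volume table, computed as
three directional cumulative sums), because (i) in 1D it reduces
exactly to the ascending/descending cumulative sums of the textbook
construction, and (ii) each bin value is then geometrically
interpretable as a box count, which is what makes the brute-force
equality oracle in the test suite possible. A neighbour-accumulation
recurrence without the inclusion–exclusion correction would inflate
counts by the number of lattice paths and was rejected.

The 8 cumulatives are merged by the per-bin **minimum** and min–max
normalized onto [0, 1] (an all-constant merged array maps to all
zeros rather than dividing by zero). The minimum is what creates the
desired anisotropy: a bin just outside the receptor surface has at
least one corner box that contains no atoms (value 0), while a bin in
the interior — even inside a closed cavity — has every corner box
populated. The interior of a hollow shell is therefore *filled* with
high values: that is by design, since an atom reaching into the
receptor core must be penalized even if the core itself is locally
empty. The test suite asserts this orientation explicitly (centre of
a shell above its wall sliver, outside exactly zero).

## Scoring and classification

A pose score is the sum over all atoms of the scored subunit
(conventionally `"Ub"`; optionally the whole ligand) of the merged
grid value at each atom's bin; atoms outside the box contribute 0.
Consequences that the tests pin down exactly: a non-contacting pose
scores exactly 0; scores are exactly additive over atoms; scores are
invariant under atom reordering; and pushing a probe from outside a
solid-ball receptor to its centre gives a non-decreasing score.

Ensemble scoring superposes each frame's histone-subunit Cα atoms onto
the reference linker histone by Kabsch least squares (proper rotations
only; the reflection branch of the SVD is sign-corrected) and applies
the transform to the whole ligand. When ligand and reference Cα counts
differ, matching falls back to a global Needleman–Wunsch alignment
with BLOSUM62 and affine gaps (open 10, extend 0.5); for near-identical
linker-histone sequences the matched set is insensitive to these
parameters, which is why a single-matrix global alignment stands in
for a multi-aligner consensus. When counts match, all 1:1 pairs in
residue order are used. Frames are independent by contract: any
chunking of the frame list yields identical results, and the
`chunks` argument is a wall-time knob only.

Classification uses two configurable cutoffs, default (100, 150):
`score < 100` is *fitting* ("lower than 100"), `100 <= score < 150`
*marginal* (typically DNA-linker contacts that could be relaxed by
minimization), `score >= 150` *non-fitting*. The published score scale
depends on receptor size and bin width, which is exactly why the
cutoffs are parameters rather than constants.

## Receptor preparation and array placement

`prepareReceptor()` splits a chromatosome into receptor (everything
except the linker-histone chain) and the reference linker histone.
Waters and monoatomic HETATM residues (ions) are excluded by default —
crystallographic solvent is not part of the steric envelope a modeled
ligand should respect — while polymeric heteroatoms are kept.

For nucleosome arrays without linker histones,
`placeReferenceHistone()` transfers a reference chromatosome's linker
histone into the array frame: each mapped core-histone chain pair is
globally aligned, the longest uninterrupted run of *identically*
aligned residues is extracted (identity is required so that an
unrelated or scrambled chain cannot contribute a spurious gap-free
1:1 correspondence), runs shorter than 5 residues exclude the chain,
the surviving Cα pairs of all chains are pooled into one Kabsch fit,
and the transform is applied to the linker histone. Manual
per-nucleosome rotation adjustments are curation, not algorithm, and
are not reproduced.

# Collective variables

Two per-frame descriptor sets characterize the histone–ubiquitin
geometry without using the full set of all pairwise Cα distances
(11 325 pairs for a 151-residue fusion, most of them redundant):

* **SASA-CVs**: Euclidean distances between every surface-exposed
  histone Cα and every surface-exposed ubiquitin Cα, flattened
  row-major (histone outer, ubiquitin inner). Exposure is decided on a
  reference conformation by per-atom Shrake–Rupley SASA — a
  deterministic Fibonacci sphere lattice (default 960 points, probe
  1.4 Å, Bondi-type radii), quadrature error below 1% for an isolated
  sphere. The exposure threshold defaults to 1 in the configured unit;
  both Å² and nm² modes exist and are recorded in the selection object,
  because the selection cardinality (and hence the CV dimension, 304
  for a 16 × 19 reference selection) depends on the unit convention.
  The threshold is per-atom SASA of the Cα atom itself, not per
  residue.
* **RMD-CVs**: for each histone Cα, the minimum distance to any
  ubiquitin Cα (row minima of the cross-subunit distance matrix),
  giving one value per histone residue (75 for the globular domain)
  regardless of ubiquitin's size.

Both are invariant under rigid motion of a frame and non-negative;
property tests assert the row-minimum bound and the rigid-motion
invariance on random frames.

# Conformational states by iterative refinement

The 2D projection of the ensemble is clustered with HDBSCAN. No R
implementation of HDBSCAN is available in this package's dependency
set, so the algorithm is implemented here in full: core distances (k-th
nearest neighbour, default `minSamples = 5`, recorded in the
documentation because the reference libraries couple this parameter to
the minimal cluster size, which is inappropriate at the artifact pass
size of 1000), mutual-reachability distances, a Prim minimum spanning
tree computed without materializing the distance matrix, single-linkage
condensation at the minimal cluster size, and excess-of-mass flat
cluster selection with the root excluded. The implementation was
cross-validated against an independent reference implementation on
Gaussian-blob benchmarks during development (mutual ARI 0.98); the
shipped tests assert planted-structure recovery, minimal-size
guarantees, noise handling and determinism.

## The pass schedule

Eight passes total: one artifact-exclusion pass at minimal cluster
size 1000, then refinement at 750, 500, 250, 125, 75, 50, 25. The
artifact pass removes clusters that are dense in 2D but structurally
heterogeneous (mean Cα RMSD to the RMSD centroid above the threshold):
these are projection artifacts, many dissimilar structures collapsed
onto one patch. Each refinement pass runs HDBSCAN on the pool of
still-unassigned points; accepted clusters freeze their labels,
rejected clusters dissolve back into the pool so a smaller pass can
resolve their substructure. Points never accepted are labelled -1.

## Acceptance criteria

A candidate cluster is rejected if **any** of:

1. mean RMSD between the cluster's RMSD centroid (the member frame
   minimizing the row sums of the pairwise minimized-RMSD matrix; ties
   broken toward the lowest frame index) and the other members exceeds
   6 Å;
2. the Fisher–Pearson skewness (g1 = m3 / m2^1.5) of the member
   distances, in the 2D projection, from the centroid's point exceeds
   0.5;
3. that same 2D distance distribution is multimodal.

Thresholds are strict inequalities: values exactly at 6 or 0.5 pass.
The multimodality gate applies to the 2D distance distribution — the
same distribution tested for skewness; the dip p-value of the RMSD
distribution is recorded in the diagnostics but does not gate.
Pairwise RMSD matrices use Cα atoms only (tractability; the atom set
is a parameter).

## The multimodality statistic

The gate uses a dip-type statistic defined precisely as the **split-fit
dip**: the smallest sup-norm band half-width around the empirical cdf
such that, for some split point, the part left of the split admits a
convex nondecreasing fit and the part from the split onward a concave
nondecreasing fit, with a free jump (the mode atom) at the split. This
is Hartigan's dip up to the treatment of the monotone coupling at the
mode atom; the split-fit convention makes the statistic *exactly*
computable by two incremental convex-hull scans (O(m²), C++), and the
test suite verifies it to machine precision against an independent
linear-feasibility oracle of the same definition. Significance comes
from a seeded Monte-Carlo null of uniform samples of the same size
(the classical least-favourable unimodal null; default 199
replicates, α = 0.05). Because observed statistic and null use the
same definition, the test has exact level regardless of the
convention.

# Expansion-scheme support

`selectRestarts()` bins the projection on a regular grid (default
30 × 30 over the bounding box — the resolution is open in the source
protocol and therefore a parameter), ranks non-empty bins by ascending
occupancy with seeded tie-breaking, and draws one seeded-uniform frame
per bin in rank order until the requested count (20 per expansion step
in the published campaigns), cycling over sparse bins without
repeating frames if needed. One frame per bin, rather than several
per sparsest bin, maximizes spatial spread of the restarts; that
choice is the package's own. The full stop–reproject–restart loop
belongs to the MD engine and is not reproduced;
`totalSimulationTime()` provides the campaign bookkeeping
(variants × starting runs × length + rounds × continuations + long
runs, reported in µs).

# Synthetic data: what it emulates, and what it does not

All generators are deterministic under a seed and return a manifest
sufficient to reconstruct the ground truth.

* `shellReceptor()` — uniform shells/solid balls standing in for the
  receptor's steric envelope, with analytic inside/cavity/outside
  classification for probes.
* `toyLigand()` — Cα-only two-subunit ligands whose ubiquitin chain is
  translated a controlled depth into the receptor; depth 0 clears it
  entirely. Toy "residues" are ideal 3.8 Å Cα chains; SASA tests use
  dedicated sphere fixtures instead, since Cα-only chains have no
  packed core.
* `toyTrajectory()` — planted conformational clusters: helical Cα
  templates whose (turn, rise) parameters are max–min spaced so that
  template pairs differ by large minimized RMSD (the generator
  *checks* the declared separation rather than assuming it), noisy
  copies per cluster, uniform-disk 2D blobs, and background frames at
  the fringes of the map. Placing noise at the fringes mirrors how the
  projection method treats isolated transition structures; it also
  means the fixtures do not probe the regime where dense clusters sit
  inside a uniform noise bath, in which any density-based flat
  labelling absorbs boundary points. A `mergedBlob` mode plants the
  refinement scenario (two structural groups sharing a double-disk 2D
  region beside one clean cluster of twice the population, so the
  largest pass performs a true split and must reject the heterogeneous
  half), and `nArtifact` plants a dense structurally-diverse patch for
  the artifact pass.
* `ringPoints()` — the classic 500-point noisy ring (r = 3, σ = 0.2)
  used to illustrate the cumulative-histogram construction.

Passing tests on these fixtures demonstrates the algorithms' contracts
— exact grid arithmetic, recovery of planted structure, correct
gating — not performance on real chromatosome data, whose projections
are non-uniform, whose clusters have irregular shapes and whose
receptor surfaces are far from spherical.

# Numerical choices and degenerate inputs

* Kabsch refuses fewer than 3 points and collinear point sets (the
  rotation is not unique); the determinant correction forbids
  reflections. Minimized RMSD is not a metric; no triangle inequality
  is asserted anywhere.
* Grid normalization guards the all-constant case (empty receptor →
  all-zero grid).
* Internal residue indexing is 0-based and contiguous per chain;
  original PDB numbering is kept alongside and used at all API
  boundaries (biological numbering such as K30 refers to `resno`).
* Alternate locations: blank or 'A' kept, others dropped. Hydrogens
  are used as present in the file — united-atom vs all-atom
  conventions are the caller's responsibility.
* Atom serials above 99 999 are written PDB-wrapped modulo 100 000;
  internal serials are unaffected.
* Scoring-grid files are a one-line JSON header plus values in flat
  x-fastest layout, all numerals printed at full precision
  (`%.17g`) so the round-trip is exact.
* All stochastic steps (generators, dip null, restart draws) flow from
  explicit integer seeds; HDBSCAN and the grid pipeline are
  deterministic by construction.

# Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
to exercise every contract with comfortable margins: random receptors
up to 500 atoms on grids up to 12³ for exact-oracle comparison (50
replicates), 100-pair superposition recovery at 1e-8 Å, planted
cluster recovery on 4 500-frame ensembles (2 × 2000 + 500 background)
under the full 8-pass schedule, and the merged-blob fixture at
400/400/800 frames. The headline numbers of the source study (score
ranges over half a million conformations against crystallographic
receptors, hundreds of accepted clusters) require the original ~35 µs
of MD data and external structures and are represented here
qualitatively by the property suites.

# Known limitations

* The ISA score is purely repulsive-geometric: no attractive terms, no
  electrostatics, no relaxation of marginal poses.
* Flat cluster extraction labels every point that falls out of a
  selected density cluster, including low-density stragglers attached
  above the cluster's birth level; on maps where sparse background
  directly abuts a dense cluster this inflates the skewness
  diagnostic, which the refinement gate then treats as
  heterogeneity — a conservative failure mode.
* The split-fit dip convention differs from Hartigan's statistic by
  the mode-atom coupling term (of order 1/n on unstructured samples);
  p-values are exact for the statistic as defined, and gate decisions
  on clearly unimodal/bimodal inputs are unaffected.
* mmCIF input, topology building and bond perception are out of scope;
  PDB is the interchange format.
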