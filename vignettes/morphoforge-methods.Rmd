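---
title: "Growing and analyzing neuronal trees as locally optimized graphs"
author: "morphoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing and analyzing neuronal trees as locally optimized graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoforge)
```

## The model

morphoforge treats a dendritic (or axonal) tree as a rooted geometric graph:
nodes carry positions in µm, diameters and region labels, and every edge
points away from a single root.  Synthetic trees are grown over a set of
unconnected *carrier points* by a greedy extension of Prim's minimum
spanning tree algorithm.  At every step, the cheapest pair of an unconnected
carrier point $p$ and an admissible tree node $v$ is connected, under the
cost

$$\mathrm{cost}(p, v) \;=\; \lVert p - v\rVert \;+\;
  \mathit{bf}\,\bigl(\mathrm{PL}(v) + \lVert p - v\rVert\bigr),$$

where $\lVert p - v\rVert$ is the Euclidean wiring cost, $\mathrm{PL}(v)$ is
the path length from the root to $v$ along the tree, and the *balancing
factor* $\mathit{bf} \ge 0$ — the single parameter of the model — weighs
conduction time (path length to the root) against material.  The second
cost is written as the full path length to the new point, so the new edge
is counted inside it; this is equivalent to the common
$\lVert p-v\rVert + bf'\,\mathrm{PL}(v)$ form up to a rescaling of the
balancing factor, and the choice is fixed here so that reported $bf$ values
are comparable across analyses.

At $\mathit{bf} = 0$ the rule *is* Prim's algorithm and the result is the
exact Euclidean minimum spanning tree over root and carriers (this is the
package's defining calibration, tested against an independent Prim
implementation to $10^{-9}$ µm).  As $\mathit{bf}$ grows, trees shift from
wide space-filling spirals toward direct, stellate connections from the
root; the mean tortuosity (path length divided by Euclidean distance to the
root) decreases monotonically.

Two additions are used when reproducing biological cell classes:

* **Multifurcation suppression** (`growthParameters(maxChildren = 2)`, the
  default): non-root nodes accept at most two children.  The root is exempt
  by default because somata emit several stems; cap it with
  `maxChildrenRoot`.
* **Determinism**: cost ties are broken toward the smallest carrier index,
  then the smallest node label, so identical inputs always give identical
  trees.  There is no distance cutoff by default (`cutoff = Inf`); all
  carriers are connected.

Where the shape of a neuron comes from, in this picture, is the *spanning
field*: the region and density profile from which carrier points are drawn.
Cell classes are data, not code — a `FieldSpec` (JSON-serializable)
describes a uniform disc or box, a ring-in-disc density, an elliptical cone
intersected with a sphere, or an arbitrary empirical density grid estimated
from real populations with `densityCloud()` and resampled with
`sampleEmpirical()`.

## Canonical representation

Comparing trees requires a unique representation; four operations provide
it.

**Label sorting** (`sortLabels`).  Nodes are ordered depth-first from the
root; at each branch point the sub-tree with the larger *topological depth*
— the sum of path-length values over all nodes of the sub-tree — is visited
first.  A leaf therefore scores its own path length; this resolves an
ambiguity in the verbal definition ("sum over all children") in the way
that makes the canonical form total.  Exact depth ties are broken by larger
sub-tree size, then by the smallest original node index, purely so the
ordering is a total order; for continuous geometry, ties essentially never
occur.  The resulting labelling is hierarchical (child labels exceed parent
labels), sub-tree contiguous, idempotent and invariant to the storage order
of the input nodes.

**Resampling** (`resampleTree`).  Nodes are redistributed at equal
inter-node distances $d$.  All topological points (root, branch points,
terminals) are kept; within each branch, new nodes are placed along the
original path and intervening continuation nodes are dropped.  Without
length conservation, every edge is a chord of the original path and hence
at most $d$ long.  With `conserveLength = TRUE`, each branch receives the
compensated nearest-integer number of $d$-segments for its arc length — for
a terminal branch this is exactly "lengthen the branch by $d/2$, then cut
at the last multiple of $d$" — and a running residual carries the rounding
residue from branch to branch so errors cancel instead of accumulating.
Finally every straightened segment is radially elongated about its parent
node (processed root-outward in label order) to exactly $d$.  The output
has all edges equal to $d$ to machine precision and conserves total cable
length to within half a sampling distance per terminal branch.  An earlier
variant that kept retained nodes on a single global lattice of root path
length was rejected: it forces branch points onto the previous sample node
and double-counts the shared cable tail at every branch point, which
measurably breaks length conservation.

**Electrotonic equivalent** (`equivalentTree`).  A unique planar layout:
each node is placed at its parent plus its original edge length along the
direction $\theta(\ell) = \pi(\ell - 1)/(N - 1)$, a strictly increasing
function of the canonical label $\ell$ over a half circle (any strictly
monotone map would preserve the properties that are tested).  Path lengths
to the root, and therefore the passive electrotonic signature at uniform
diameter, are unchanged.

**Topological gene** (`topologicalGene` / `treeFromGene`).  The canonical
one-dimensional encoding: branches in label order, each as its metric
length followed by `B` (ends in a branch point) or `T` (ends in a
termination).  For binary trees the string determines topology and branch
lengths completely.  One subtlety is documented rather than hidden: the
sibling order induced by the depth score depends on how many nodes lie on
each branch, so a gene read from an arbitrarily sampled tree is not
automatically in canonical order for the single-edge-per-branch tree that
`treeFromGene` rebuilds.  One stabilization pass
(`topologicalGene(treeFromGene(g))`) lands in the fixed point, on which the
roundtrip is exactly the identity; branch lengths and topology are
preserved from any well-formed gene.

## Steady-state electrotonics

The electrotonic signature is the node-by-node matrix of steady-state
potentials: invert the passive conductance matrix $G$ and scale by the
injected current (1 nA by default), reported in mV.  $G$ has the axial
conductances of the edges off the diagonal
($g = \pi d^2 / (4 R_a L)$ for a cylinder; the edge diameter is the mean of
its two node diameters, since frusta are declared in the data model but no
frustum formula is prescribed) and on the diagonal each node's adjacent
axial conductances plus its membrane leak.  Membrane area is lumped as half
the lateral cylinder area of every adjacent edge, the standard
compartmental partition; ends are sealed.  All µm-to-cm unit conversions
happen inside the matrix builder and nowhere else.  $G$ is symmetric and
strictly diagonally dominant (every node leaks), hence positive definite
and safely invertible; dense inversion is used (trees of up to a few
thousand nodes invert in well under a second, which covers every problem
size in this package).  Default passive parameters are
$R_a = 100\ \Omega\,$cm and $R_m = 2000\ \Omega\,$cm² (an insect-dendrite
set); cortical pyramidal models typically use $R_m = 20000\ \Omega\,$cm².

Validity is checked against independent physics: reciprocity
($V = V^\top$), per-column linear solves versus full inversion, the
iso-potential closed form $V = I R_m / (\pi d L)$ (realized as a two-node
cylinder with negligible axial resistivity), and the infinite-cable input
resistance $R_\infty = 2\sqrt{R_m R_a}/(\pi d^{3/2})$ approached by a
sealed cable of five length constants to within 1%.

**Compartment size** summarizes electrotonic compartmentalization: for
each injection node, the cable length (half of every adjacent edge is
assigned to each node, so the partition sums to the total) over all nodes
whose deflection reaches 60% of that injection's maximum, averaged over
injection sites.  Cable-length weighting (rather than node counting) is
used because the statistic is defined as an amount of dendritic length.
Grown on uniform discs of radius 200 µm (about one length constant at
default passive parameters and 1 µm diameter) with 150 carriers and
resampled at 10 µm, ensembles of 20 trees per balancing factor show mean
compartment size strictly decreasing across
$\mathit{bf} \in \{0, 0.2, 0.5, 0.85\}$ — higher balancing factors give
more stellate trees whose sub-trees are electrically more segregated.
These ensemble sizes were chosen once as the smallest that make the trend
statistically stable.

## Morphometry

* **Branch order**: number of branch points among a node's proper
  ancestors (the root counts when it emits more than one stem).
* **Sholl analysis**: intersections of the tree with root-centred spheres,
  operationalized as the number of edges whose endpoint distances straddle
  the radius, closed at the lower bound so tangent endpoints count once.
  Verified against a brute-force sign-change oracle.
* **Summary triplet** (`morphSummary` / `matchSummary`): total cable
  length, branch-point count and mean path length, with matching
  tolerances of 200 µm, 5 branch points and 3 µm — the criteria used to
  select a balancing factor and carrier count against a reference cell.
  Histograms default to 10 µm path-length bins and unit branch-order bins.
* **Population scaling** (`scaleToMeanLimits`): per region and axis, each
  cell's bounding interval is affinely mapped onto the population mean
  interval (size normalization for deriving shared spanning fields).
  Cells must already be centred on their somata and rotated into a common
  frame; rotation is accepted as an input transform, not estimated.
* **Density clouds** (`densityCloud`): binned topological points (default
  10 µm bins, one-bin Gaussian smoothing, renormalized to mass 1), the
  empirical counterpart of the parametric fields.

## Density fields

The ring density is a Gaussian in distance from the centre (area density),
truncated to the circular hull, with default width `hullRadius/4`; as the
width grows it converges to the uniform disc.  The cone-and-sphere field
intersects an elliptical cone with a sphere whose centre lies behind the
apex on the cone axis; its radial profile is a two-component Beta mixture
over the normalized apex-to-rim coordinate (mass near the origin and again
at the rim), with configurable weights and shapes — the qualitative shape
is prescribed, the functional form is this package's choice.  All samplers
are deterministic per seed, honour the requested count exactly, and
rejection samplers abort loudly after 1000 × n proposals rather than
looping forever on a degenerate region.

## Post-processing

* **Jitter** (`addJitter`): per-branch Gaussian displacement fields,
  low-pass filtered by a moving average (default window 5 nodes; the
  filter narrows on branches shorter than the window), pinned to zero at
  topological points so connectivity shows no spatial discontinuity, and
  scaled so the RMS displacement of the moved nodes equals the requested
  amplitude.  Homogeneous application requires equal segment lengths, so
  the tree must be resampled first (enforced).
* **Diameter taper** (`taperDiameters`):
  $d = d_\mathrm{tip} + (d_\mathrm{root} - d_\mathrm{tip})(1 - \mathrm{PL}/\mathrm{PL}_\mathrm{max})^2$,
  with $\mathrm{PL}_\mathrm{max}$ the path length of the farthest terminal
  through the node — quadratic in normalized path, non-increasing along
  every root-to-tip path, exact at both endpoints.
* **Soma mapping** (`mapSoma`): a raised-cosine multiplicative swelling
  over path lengths up to `extent`, equal to the target soma diameter at
  the root and continuously reaching 1 at the boundary.

## Image-based reconstruction

The growth algorithm doubles as a model-based tracer.  The pipeline is:
local thresholding (foreground iff intensity exceeds the local mean plus
$k$ local standard deviations in a cubic window; strict, with a small
numerical tolerance, so constant volumes yield nothing) → removal of
foreground components smaller than `minComponent` voxels (noise specks
pass any local threshold but genuine neurites span hundreds of voxels) →
3D skeletonization → greedy sparsening to a minimum spacing → greedy
growth from a user-given root with an image-derived pairwise cost added to
the geometric cost → pruning of terminal branches that are shorter than
3 µm or dimmer than the background floor.

Numerical choices that matter here:

* **Skeletonization** is sequential topology-preserving border peeling
  with a simple-point test (26-connectivity for the object, 6 for the
  background) and endpoint preservation, implemented in C++.  Deleting one
  simple point at a time cannot disconnect the foreground, so the skeleton
  is connected wherever the mask is.
* **Image cost**: for point pairs within 10 µm, the mean of
  (1 − normalized intensity) along the connecting line.  Samples take the
  maximum over a one-voxel neighborhood, because a straight chord between
  points on a bent, one-voxel-wide bright path inevitably clips corners;
  only a contiguous run of sub-floor samples wider than one voxel counts
  as a forbidden background crossing (`Inf`).
* **Background floor**: median + 3 MAD of the normalized volume (plus an
  epsilon so exact-zero background stays below it).  Otsu's threshold is
  deliberately not used here: signal voxels are a fraction of a percent of
  a stack, so a two-class histogram split latches onto the zero-versus-noise
  boundary instead of the noise-versus-signal one.
* Carriers that remain unreachable under the image cost (disconnected
  noise remnants) are dropped and reported via the `unconnected`
  attribute rather than force-connected across dark gaps.

Because real microscopy stacks cannot ship with the package, the renderer
(`renderTree`) provides ground truth: edges are rasterized with
diameter-proportional deposit, blurred by a Gaussian PSF and overlaid with
seeded Gaussian noise.  On noise-free renders of a 245 µm binary test tree
at 1 µm voxels the pipeline recovers total cable length within 10% (in
practice ~1%) and the branch-point count within ±2, and the length error
is non-decreasing in the noise level.  Multi-cell stacks are handled by
passing several roots to `growCompetitive` with the same image cost; no
interactive editing is provided — flagged branches are reported, not
curated.

## What the synthetic generators do and do not emulate

The carrier-point fields and the renderer emulate the *statistical*
structure of the data the methods operate on: seeded point clouds with
prescribed density profiles, and idealized fluorescence volumes with
Gaussian PSF and additive Gaussian noise.  They do not emulate tissue
boundaries or obstacle avoidance, shrinkage and fixation artefacts,
diameter-dependent partial-volume effects, depth-dependent attenuation, or
anisotropic, structured microscopy noise.  Tests passing on these inputs
therefore validate the algorithms' contracts (optimality, canonicality,
conservation laws, recovery on idealized data), not end-to-end performance
on real reconstructions or real stacks.

## Problem sizes and limitations

Test and acceptance runs use carrier sets of 30–350 points, trees up to a
few thousand nodes after resampling, and image volumes of roughly
120 × 120 × 25 voxels — sizes chosen so the full suite exercises every
code path in a few minutes on one core while keeping all statistical
checks stable under their fixed seeds.  The growth engine is the naive
O(n²) incremental algorithm; it is the reference implementation, and any
acceleration must reproduce it exactly.

Known limitations: growth is greedy, not globally optimal; there is no
volumetric packing or obstacle avoidance; diameters are cosmetic
(taper/soma mapping) rather than optimized; the electrotonic model is
passive and steady-state only; `treeFromGene` assumes binary branch points
and a single root stem; and multi-tree SWC forests are out of scope.
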