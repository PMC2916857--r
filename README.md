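# morphoforge

Generative modelling and analysis of neuronal branching as locally
optimized graphs.

Dendritic and axonal trees solve a wiring problem: use little cable, and
keep every synapse electrically close to the cell body.  morphoforge
implements a generative model built on exactly this trade-off, for
computational neuroanatomists who want to synthesize realistic
morphologies for a cell class, compare real reconstructions in a canonical
representation, analyze passive electrotonics, or trace neurons out of 3D
image stacks with a model-based algorithm.

## The core algorithm

A tree is grown over unconnected *carrier points* by a greedy extension of
Prim's minimum spanning tree algorithm.  At each step the cheapest pair of
an unconnected point *p* and an admissible tree node *v* is connected,
with

```
cost(p, v) = ||p − v|| + bf · (PL(v) + ||p − v||)
```

where `||p − v||` is the Euclidean wiring cost, `PL(v)` the path length
from the root to *v*, and the **balancing factor** `bf ≥ 0` — the single
model parameter — weighs conduction time against material.  At `bf = 0`
the output is the exact Euclidean minimum spanning tree; large `bf` gives
stellate trees with almost direct paths from the root.  Cell-class
identity comes from the *spanning field*: the spatial density (uniform
disc/box, ring-in-disc, elliptical cone ∩ sphere, or an empirical density
cloud) from which carrier points are sampled.

Around the growth model the package provides:

* a canonical tree representation: unique label sorting, equidistant
  resampling with cable-length conservation, the electrotonic-equivalent
  layout, and the one-dimensional "topological gene" encoding;
* steady-state passive electrotonics: the node×node current-transfer
  matrix by conductance-matrix inversion, and an electrotonic
  compartment-size statistic (60% deflection rule);
* morphometry: branch order, Sholl intersections, path-length
  distributions, population scaling to mean region limits, density clouds;
* competitive multi-tree growth (dendritic tiling emerges from the same
  cost rule applied across cells);
* cosmetic post-processing: low-pass-filtered spatial jitter, quadratic
  diameter taper, cosine soma mapping;
* model-based reconstruction from 3D grayscale volumes (local threshold →
  3D skeletonization → sparsening → image-cost-guided greedy growth →
  pruning), plus a synthetic fluorescence renderer for ground-truth
  validation;
* SWC input/output and a thin command-line wrapper
  (`inst/cli/morphoforge.R`).

## Worked example

Grow a planar, starburst-amacrine-like neurite on a ring-shaped density
field, summarize it, and measure its electrotonic compartmentalization:

```r
library(morphoforge)

pts <- sampleRingDisc(hullRadius = 150, ringRadius = 90, n = 250, seed = 42)
tr  <- growTree(c(0, 0, 0), pts, growthParameters(bf = 0.6))
tr
#> NeuronTree with 251 nodes (64 branch points, 67 terminals)
#>   total cable length: 3069.38 um

morphSummary(tr)
#> total cable length: 3069.4 um | branch points: 64 | mean path length: 118.8 um

rs <- resampleTree(tr, 5, conserveLength = TRUE)
compartmentSize(rs, passiveParameters())
#> [1] 238.9106
```

The 251 nodes are the root plus all 250 carriers; with multifurcation
suppression (the default) every non-root node has at most two children.
The summary triplet — total cable, branch points, mean path length — is
the statistic used to fit `bf` and the carrier count against a reference
cell (`matchSummary`).  The compartment size says that, per injection
site, on average 238.9 µm of cable stays above 60% of the peak potential
deflection; growing the same field with a higher `bf` yields smaller
compartments (more electrically segregated sub-trees).

Write the cell to disk with `writeSWC(tr, "cell.swc")`, encode its
topology with `topologicalGene(tr)`, or rebuild a tree from a gene with
`treeFromGene()`.

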