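---
title: "Quantifying network correspondence between brain maps and atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying network correspondence between brain maps and atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcorr)
```

## The problem

Human functional MRI research describes results in terms of large-scale
networks — "default", "salience", "frontoparietal" — but different research
groups delineate and name these networks differently. The same cortical
territory can carry half a dozen different labels across published atlases,
and the same name can refer to substantially different territory. When a new
finding is reported against one atlas, readers anchored to another cannot
easily tell what was found.

`netcorr` addresses this by making the correspondence explicit and
quantitative: given a user's spatial map (a thresholded statistic map or a
network from a hard parcellation) and a set of reference atlases, it reports
how strongly the map overlaps each named network of each atlas, and whether
that overlap is more than would be expected for maps with the same spatial
structure placed randomly on the cortex.

## Overlap model

All comparisons happen in a single **reference space** — always the space of
the input data; atlases are projected into it by nearest-neighbour label
resampling on the registration sphere, never the reverse. Spatial
correspondence between two binary regions $A$ and $B$ is the Dice
coefficient

$$ D(A, B) \;=\; \frac{2\,|A \cap B|}{|A| + |B|} \in [0, 1], $$

with $0$ meaning no correspondence and $1$ total correspondence. For a
reference object with $K$ rows (networks of a reference atlas, or input-map
dimensions) against an atlas with $M$ networks, the package assembles the
$K \times M$ matrix of pairwise Dice values. Non-cortical (medial-wall)
locations and the background label $0$ are excluded from both numerator and
denominator. Two empty masks have Dice $0$ by convention (avoiding $0/0$);
this only arises in degenerate inputs.

For readability, `order_by_best_match()` permutes the columns so each
reference network faces its best-overlapping partner on the diagonal. The
assignment is greedy — rows claim columns in descending order of their row
maximum, without column reuse, ties to the lowest original column index.
Greedy assignment is deterministic and, for the near-diagonal matrices that
arise in practice, indistinguishable from an optimal assignment; it is a
presentation device, not an inferential step.

When many atlases are compared all-vs-all, each ordered pair (reference,
other) produces its own matrix — $n$ atlases give $n(n-1)$ matrices — and
`stack_similarity()` assembles the square all-network similarity matrix.
That matrix is deliberately **not symmetric**: block $(i, j)$ is computed in
atlas $i$'s space and $(j, i)$ in atlas $j$'s, and the discrepancy between
the two triangles is itself informative about projection effects.

## Spin-test significance

A Dice value alone does not say whether an overlap is meaningful: smooth
cortical maps overlap by chance. The package uses the spin test — the input
map is randomly rotated over the registration sphere `n` times (default
1000), each rotation preserving the map's shape, size and internal spatial
autocorrelation, and the Dice coefficient is recomputed against the fixed
network. The p-value is

$$ p \;=\; \frac{\#\{i : D_i^{\text{null}} > D^{\text{obs}}\}}{N}, $$

the fraction of rotations whose Dice strictly exceeds the observed value.
This is the exact convention implemented; the minimum attainable p is 0. A
conservative $(c+1)/(N+1)$ variant is available via
`variant = "plus-one"`. Ties (null Dice exactly equal to observed) count as
*not larger*; with very small masks on coarse meshes this can concentrate
probability mass (many rotations give Dice exactly 0) and make the test
anti-conservative in degenerate cases — see *Calibration* below.

Design choices that matter:

* **Rotation sampling.** Uniform over SO(3), by QR orthonormalization of a
  standard-normal $3\times3$ draw with sign and determinant correction.
  One rotation is sampled per permutation; on a two-hemisphere mesh the
  left side receives $R$ and the right side the mirror conjugate
  $XRX$, $X=\mathrm{diag}(-1,1,1)$, preserving bilateral symmetry (the
  established convention in the spin-test literature).
* **The data map is rotated, not the atlas**, and one rotation set is
  shared across every cell of a result matrix, so all (map, network) tests
  see the same null.
* **Off-cortex handling.** After rotation, a vertex whose source lands on
  the medial wall carries no information. Such vertices are excluded from
  the Dice computation entirely — from both the rotated map and the network
  mask — rather than counted as "absent". Counting them as absent would
  shrink every null Dice by the wall fraction and bias p-values downward.

### Calibration

The test's type-I behaviour is checked by simulation
(`spin_calibration()`): a template parcel is rotated by a fresh uniform
rotation to create an input map that is, by construction, spatially
unrelated to the target network, and a full spin test is run. Repeating
this yields p-values that should be uniform. Two details make the check
exact rather than approximate. First, each replicate uses its own
independently seeded rotation set; sharing one set across replicates would
correlate the replicate p-values and distort the uniformity check. Second,
the rotated data mask's observed Dice is computed under the same
remap-and-exclude convention as the null draws (as the first of $N+1$
independent spins), so observed and null statistics are exchangeable by
construction; mixing conventions — an unremapped observed mask against
remapped nulls — introduces a small systematic rank bias.

Two properties of the fixture matter and are documented here because they
generalize to real data:

* The template parcel must occupy an appreciable fraction of the cortex
  (the calibration fixtures use one parcel of a 3-network Voronoi
  parcellation, roughly a third of the cortical surface). Tiny parcels
  make "zero overlap" a common outcome, and an atom of exact ties at Dice 0
  cannot be spread into a uniform p-distribution by any convention.
* The calibration is run at the package's standard desk-scale problem
  size: the subdivision-4 icosphere (2,562 vertices, ~5% medial wall),
  200 rotations per test, 200 replicates. These sizes give a Kolmogorov–
  Smirnov uniformity check adequate power while keeping the simulation in
  the minutes range.

## Thresholding metric maps

Hard parcellations enter the pipeline as label masks; continuous maps
(e.g. z-statistics) must be binarized first. Two routes are provided:

1. **Fixed cutoff** — `threshold_map(map, tau)` keeps locations with value
   $\ge \tau$ (inclusive; the choice of inclusive over strict is
   inconsequential for continuous data and is fixed for determinism).
2. **Mixture model** — `fit_mixture()` models the intensity histogram as
   background noise plus signal: a Gaussian null, a shifted Gamma for
   activation (support above the null mean) and a mirrored shifted Gamma
   for deactivation. This is the classic ICA spatial-map convention. A
   location is kept if its posterior probability of belonging to either
   signal component reaches the cutoff, default **0.6** — slightly
   favouring signal identification over noise, with 0.5 weighing the two
   equally; on well-separated maps the two cutoffs select nearly identical
   masks.

EM details (this module's own choices): initialization by moment-matching —
null mean/sd from the central 80% of values, signal components from the
tails; Gamma shifts anchored at the initial null mean and held fixed; the
Gamma M-step solves the weighted maximum-likelihood shape equation by
Newton iterations on $\log k - \psi(k)$, so every step is an exact M-step
and the log-likelihood is non-decreasing; convergence when the
log-likelihood improves by less than `tol = 1e-6`, capped at
`max_iter = 500`; components whose weight falls below $10^{-4}$ are pruned
so the fit reduces gracefully to null+positive or null-only; maps with no
negative values skip the deactivation component from the start. The fit is
fully deterministic — there is no random initialization.

The parametric family (Gaussian + two shifted Gammas) is a convention, not
a ground truth; maps thresholded elsewhere with a different family will not
reproduce voxel-for-voxel. Parameter recovery is verified by simulation:
on draws from $0.8\,\mathcal{N}(0,1) + 0.2\,(2+\Gamma(4,1))$ the null
weight is recovered within $\pm 0.05$ and the null sd within $\pm 0.1$.

## Cross-atlas clustering

To examine naming consistency across many atlases, all networks from all
atlases are clustered on their pairwise Dice similarity. The package uses
**average-linkage agglomerative clustering** on the distance $1 - S'$,
where $S' = (S + S^\top)/2$ symmetrizes the stacked similarity matrix
(arithmetic-mean symmetrization; the two triangles differ only by
projection direction). Hierarchical model-based alternatives (stochastic
block models) exist and can produce different partitions; the clustering
backend sits behind `cluster_networks()` so another engine can be
substituted. The default cluster count is the rounded mean network count
across the input atlases (`default_n_clusters()`).

Each cluster is summarized by a **probability map**: the value at a vertex
is the fraction of contributing atlases that assign the vertex to any
member network of the cluster, each atlas counted at most once per vertex.
Values are therefore rational with denominator equal to the number of
contributing atlases; an interior plateau near 1 with a fractional boundary
band indicates strong cross-atlas concordance. These maps summarize
convergence between existing atlases — they are not a new consensus atlas.

## Synthetic data: what it emulates, what it does not

Everything above is testable without any external template because the
package generates its own study materials:

* `build_icosphere(s)` — geodesic subdivision of the icosahedron,
  $V = 10\cdot4^s + 2$ vertices; subdivision 6 matches the fsaverage6
  vertex count (40,962). A contiguous south-polar cap of ~5% of vertices is
  flagged non-cortical to emulate the medial wall. Real meshes and masks
  can be supplied instead via `sphere_mesh()`.
* `generate_synthetic_atlas(mesh, K, seed, jitter)` — spherical Voronoi
  parcellation from `K` uniformly drawn cortical seed vertices. `jitter`
  displaces each seed along a random tangent direction by a fixed angle
  (radians) before assignment, producing families of correlated atlas
  variants that mimic related published parcellations (the `variant`
  argument draws independent jitter directions for multiple variants of
  one template).

The fixtures reproduce the *geometry* of the problem — spherical topology,
medial-wall exclusion, resampling between mesh densities, multi-atlas
families with controlled similarity — but not the *anatomy*: real networks
are spatially distributed (not convex Voronoi cells), bilaterally
organized, and have boundary uncertainty that is not isotropic. Passing
tests therefore validate the algorithms and their statistical calibration,
not any neuroscientific claim about particular atlases.

## Numerical conventions and degenerate inputs

* Nearest-vertex queries: exact search; ties at exactly equal distance go
  to the lowest vertex index.
* Resampling targets whose nearest source vertex is non-cortical become
  unassigned (0), as do medial-wall targets.
* Dice of two empty masks is 0.
* Greedy best-match ordering ties break to the lowest original column
  index; an all-zero row claims the lowest-index remaining column.
* Clustering merge-distance ties follow the `hclust` lowest-pair-index
  convention; partitions are equivariant under simultaneous row/column
  permutation of the similarity.
* All randomness (rotation sets, synthetic atlases, sub-seeds of the
  acceptance script) flows from explicit integer seeds; every pipeline
  stage is bit-reproducible given the seed, and two CLI runs with the same
  seed produce byte-identical CSV/JSON outputs.

## Problem sizes

The test-suite and acceptance computations use the subdivision-3 and -4
icospheres (642 / 2,562 vertices), 16-atlas registries for the all-pairs
bookkeeping, 200-rotation × 200-replicate spin calibrations, $10^5$-value
mixture fits over 10 seeds, and 8-atlas jittered families for clustering
recovery. These sizes were chosen so each property has enough resolution
to fail visibly if the implementation is wrong, while a full run stays in
the minutes range on a single CPU. The same code paths scale to
fsaverage6-density meshes (subdivision 6) unchanged.

## Known limitations

* Nearest-neighbour resampling is the only built-in projection;
  volume-to-surface and nonlinear template-to-template mappings must be
  supplied as precomputed correspondence tables
  (`read_correspondence_table()`); there is no built-in volumetric spin
  test — volumetric inputs must be projected to a surface first.
* The GIFTI reader/writer handles ASCII-encoded data arrays (sufficient
  for label/metric/surface exchange and for keeping fixtures plain-text);
  Base64/compressed GIFTI and CIFTI dense containers are not parsed.
* The spin test assumes the map lives on a registration sphere; maps on
  strongly distorted meshes violate the area-preservation assumption of
  rotation nulls.
* Uncorrected p-values are reported by default (with an optional
  Bonferroni flag), matching common practice of starring uncorrected
  p < 0.05; users comparing against many atlases should consider the
  multiplicity.
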