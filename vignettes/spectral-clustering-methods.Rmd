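---
title: "Spectral geometry of molecular surfaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral geometry of molecular surfaces: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molspec)
```

# The method in one paragraph

molspec clusters small molecules by the intrinsic geometry of their
solvent-accessible surfaces (SAS). Each molecule becomes a triangle mesh;
the mesh carries a discrete Laplace–Beltrami operator whose low
eigenpairs are an isometry-invariant shape signature (the "shape-DNA"
idea); curvature-weighted sampling condenses the eigenvector matrix into
a fixed-size feature matrix per molecule; an unsupervised embedder (a
deep belief network or one of three autoencoders) maps those matrices to
a latent space; k-means partitions the latent points; six internal
validity indices score the partition; and three nonparametric k-sample
tests ask whether classical topological descriptors of the molecular
graph differ across the clusters.

# Surfaces and meshes

The van der Waals surface is the boundary of the union of atomic spheres
at empirical (Bondi) radii. The SAS used here is the same union after
inflating every radius by the probe radius `r` (default 1.4 Å, the
effective radius of water): the locus where the *signed distance field*

$$f(p) = \min_i\left(\lVert p - c_i\rVert - (r_i + r)\right)$$

vanishes. With `probe = 0` the same machinery meshes the van der Waals
surface. This union-of-balls surface is deliberately simpler than the
re-entrant (Connolly) surface: it is exactly the zero level set of a
cheap, smooth-enough field, and every downstream quantity is intrinsic
to whatever surface is supplied.

Meshing samples `f` on a regular grid (default spacing 0.5 Å, bounding
box padded by the largest inflated radius plus two cells) and extracts
the zero level set with a *marching-tetrahedra* scan: each grid cell is
split into six tetrahedra around a fixed main diagonal, so adjacent
cells share face diagonals and the triangulation is watertight wherever
the surface stays inside the grid. Within a tetrahedron the interpolated
field is linear, which gives exact intersection points, an exact per-tet
gradient for outward orientation, and vertex welding by grid-edge
identity (no epsilon merging). Degenerate triangles (area below
1e-10 Å²) are dropped and coincident vertices merged. All surface
components are kept by default — the inflated union of a connected
molecule can still enclose cavities — with `keep_largest_only` as an
opt-out.

Grid resolution is the accuracy dial: for a single atom (a sphere of
radius `r_i + r`) the mesh area at 0.4 Å is within 0.5% of the analytic
value, and the area error shrinks roughly quadratically with the
spacing. Meshes are open books: `mesh_stats()` reports vertex, edge,
face, boundary-edge and component counts, the Euler characteristic and
total area; writers for PLY/OBJ/OFF are included.

# The discrete Laplace–Beltrami operator

`assemble_laplacian()` uses the classical cotangent scheme: edge weight
$w_{uv} = \tfrac12(\cot\alpha_{uv} + \cot\beta_{uv})$ from the angles
opposite the edge in its (at most two) incident triangles — boundary
edges keep the single available angle — and barycentric vertex areas
$A(v)$, one third of the incident triangle areas, which partition the
total area exactly. The operator follows the positive semi-definite sign
convention (diagonal $\sum_k w_{ik}/A_i$, off-diagonal $-w_{ij}/A_i$),
so eigenvalues are nonnegative, ascending order is meaningful, and the
kernel dimension equals the number of connected components.
Near-degenerate triangles (|sin| below 1e-12) have their cotangents
clamped at ±1e12 with a warning rather than poisoning the matrix.

`eigendecompose()` solves the generalized symmetric problem
$S\phi = \lambda A\phi$ (equivalent to the non-symmetric $A^{-1}S$ but
numerically stable) for the `N` smallest eigenpairs, returning
`A`-orthonormal eigenvectors with a deterministic sign (largest-magnitude
entry positive). Below 900 vertices a dense LAPACK solve is used. Above
it, a shift-inverted blocked subspace iteration: sparse Cholesky of
$S_{sym} + \tau I$ (with $\tau$ = 1e-6 of the mean diagonal), a fixed
quasi-random start basis, one solve per QR re-orthogonalization, and
Rayleigh–Ritz extraction every third sweep. One solve per sweep matters:
the inverted spectrum is dominated by the near-kernel mode, and stacked
solves between orthogonalizations would erase the trailing
eigendirections. Convergence is declared when the largest Ritz-value
change, scaled by the spectral magnitude, falls below 1e-10 — a
spectrum-scaled rather than per-value criterion, because the kernel
eigenvalue is numerical noise around zero and can never meet a relative
tolerance. The iteration is bit-reproducible across runs, which a
Lanczos library with internal workspace state is not; on meshes where
both fit, sparse and dense eigenvalues agree to ~1e-11 relative. The
default `N = 32` eigenpairs is a compromise: the first ~10 nonzero
eigenvalues carry most of the gross-shape information (on a unit sphere
they reproduce the $l(l+1)$ bands to better than 3% at subdivision 4),
while higher modes add fine detail that is increasingly mesh-dependent.

# Curvature and sampling

The sampling weight is the magnitude of the discrete *mean-curvature
normal*, $H(v) = \lVert\sum_u w_{uv}(v-u)\rVert / (2A_{mix}(v))$, with
Meyer's mixed (Voronoi-style) vertex areas. Two numerical choices here
are worth stating. First, the mixed area rather than the barycentric one:
on a unit icosphere the barycentric normalization is ~14% off at the
twelve valence-5 vertices, while the mixed area gives $H = 1/R$ to five
digits; both partitions sum to the same total area, so only the
curvature, not the Laplacian, uses the mixed rule. Second, boundary
vertices get $H = 0$: their one-ring is incomplete, the formula is
meaningless there, and zeroing them both keeps flat open patches exactly
at zero curvature and prevents mesh-boundary artefacts from soaking up
sampling probability. A `"literal"` variant — the edge-length-weighted
cotangent sum — is retained behind an argument; it is scale-dependent
and nonzero on planes, so it is not the default. An identically zero
field (a flat patch) falls back to uniform weights with a warning.

Curvatures are clamped at zero and normalized into a probability
distribution, and `weighted_sample()` draws 200 vertices (or all, if the
mesh is smaller) without replacement by Efraimidis–Spirakis keys
$u^{1/w}$ — a pure function of (weights, seed), so a run is reproducible
from one integer. For a single draw the inclusion law is exact: over
many seeds the empirical pick frequencies match the weights to Monte
Carlo error.

`build_feature_matrix()` restricts the eigenvector matrix
$\Phi = [\phi_1|\cdots|\phi_N]$ to the sampled vertices, orders rows by
descending curvature (ties by vertex index), zero-pads to a fixed
200-row shape so every molecule presents the same input size, and keeps
the near-zero first eigenvector — its constant level is
$1/\sqrt{\text{area}}$ and thus encodes size.

## Why the pipeline sorts each eigenvector column

Two meshes of two different molecules share no vertex correspondence:
"the 37th-highest-curvature vertex" of one molecule has nothing to do
with the 37th of another, and eigenvector values read at those vertices
are incomparable across molecules. Empirically this is fatal at library
scale: on an 80-molecule fused-sphere library spanning four shape
classes, nearest-neighbour classification on the curvature-ordered
flattened matrices is at chance (0.31 for four classes), while the same
numbers re-ordered within each column — the order statistics of each
eigenvector over the sampled vertices — classify at 0.99. The
distribution of an eigenfunction's values is an isometry-invariant,
correspondence-free signature; the pointwise arrangement is not.
`run_pipeline()` therefore applies a `canonicalize = "column_sorted"`
step (each column of the feature matrix sorted descending) before the
embedders, with `"curvature"` (the raw row ordering) available for
workflows that do have correspondence, e.g. conformers of one molecule.
`build_feature_matrix()` itself always returns curvature-ordered rows;
the canonicalization is a dataset-level choice.

# Embedding models

All four models consume the standardized (per-feature zero-mean,
unit-variance) flattened matrices and emit a 32-dimensional latent space
by default. All training is plain R linear algebra with hand-derived
gradients, Adam (autoencoders) or momentum SGD (RBMs), minibatches, and
every random draw routed through a seeded stream: single-threaded reruns
are bit-identical.

**DBN.** A stack of RBMs (default 512–128–32) trained greedily with
CD-1. The first layer is Gaussian–Bernoulli, because the inputs are
real-valued; deeper layers are Bernoulli. The training recipe is the
standard one for CD: momentum 0.5 for five epochs then 0.9, weight decay
2e-4, learning rate 0.005 for binary layers but 0.001 for the Gaussian
layer — real-valued visible units need a much smaller step, and at 0.01
the first layer's weights blow up and the latent collapses to a handful
of binary patterns. Epochs double with depth (default 200, 400, 800):
deeper layers see much smaller inputs, so the extra sweeps are nearly
free, and the narrow top layer is by far the slowest to become a useful
code — stopping it at the first layer's budget visibly degrades the
latent clustering on the synthetic library. Greedy CD is also a lottery:
an occasional run converges to a top-layer code that reconstructs the
data poorly and scrambles its geometry (nearest-neighbour structure
survives, k-means structure does not). `dbn_train()` therefore trains
three independently seeded stacks and keeps the one with the lowest
input-space reconstruction error through the unrolled network — the same
best-of-restarts logic k-means uses, with an unsupervised criterion; in
our experiments reconstruction error separates the degenerate codes from
the good ones cleanly. Encoding is the deterministic mean-activation
forward pass.

**CAE.** Two stride-2, kernel-3 convolutions (8 then 16 channels) and a
dense bottleneck, with a mirrored transposed-convolution decoder, under
squared-error loss. Convolutions are implemented as structured sparse
linear maps — index triplets encode the weight sharing — so the same
machinery provides the forward pass, the input gradient, the kernel
gradient, and (by transposing the map) the decoder.

**VAE.** A dense trunk with Gaussian mean/log-variance heads,
reparameterized sampling, and the analytic KL to a standard-normal
prior; the loss is the negative ELBO, and the encoding used downstream
is the posterior mean. Log-variances are clamped to ±10 for stability.

**AAE.** The deterministic dense autoencoder plus a small discriminator
(64 hidden units, sigmoid output clamped away from 0/1); each minibatch
takes a reconstruction step, a discriminator step on balanced
prior/posterior batches, and an encoder-fooling step.

`joint_finetune()` implements the joint objective
$L = L_{recon} + \lambda L_{cluster}$: gradient epochs with an extra
$2\lambda(z-\mu)$ pull at the bottleneck alternate with centroid/label
updates, stopping when the joint loss stops decreasing (1e-6) or at an
iteration cap. With $\lambda = 0$ it reduces exactly to
reconstruction-only training. The pipeline default is the two-stage
regime (train, then cluster), matching how the embedder-plus-k-means
combinations are usually reported; joint fine-tuning is opt-in via
`joint_lambda`.

None of the four architectures' hyperparameters (layer widths, epochs,
learning rates, optimizers) are anchored to external values; they are
package defaults chosen once to be stable at the fixture scales below
and are all exposed as arguments.

# Clustering and validity indices

`kmeans_fit()` is Lloyd's algorithm with k-means++ seeding, ten
restarts keeping the best WCSS, relative tolerance 1e-6, and
empty-cluster repair by reseeding at the point farthest from its
centroid (never stealing a cluster's last member). It matches
`stats::kmeans` (Lloyd, same restart budget) on well-separated data; it
exists as its own loop because the seeding, determinism and repair
behaviour are part of the package's contract, and `stats::kmeans` serves
as the cross-check in the tests.

The six indices in `score_clustering()`: Calinski–Harabasz
(between/within variance ratio with its $(n-k)/(k-1)$ factor),
Davies–Bouldin ($s_i$ = mean distance to own centroid, $d_{ij}$ =
centroid distance), Dunn (single-linkage minimum inter-cluster point
distance over maximum cluster diameter — the classical reading of
"distance between clusters"), $R^2 = 1 - \text{WCSS}/\text{TSS}$, mean
silhouette (singletons score 0), and the size-weighted mean of the
per-cluster standard deviation of distances about the cluster mean (the
per-cluster quantity is standard; the size-weighted mean is this
package's convention for reporting one number). All distances are
Euclidean. Every index is verified against an independent brute-force
reimplementation to 1e-8 and against a four-point example computable by
hand (CH = 20000, DB = 0.01, Dunn = 99, R² ≈ 0.9999, silhouette ≈
0.99005).

# Topological descriptors

Descriptors are computed on the hydrogen-suppressed graph (hydrogens do
enter the surface, since they shape the SAS; they do not enter the
graph, the convention under which the classical indices were tabulated).
Six are provided, several in deliberately *compact degree-sum* forms
with the classical literature variants behind `variant = "standard"`
flags:

- branching index `balaban_j`: default $m/(n-1+\sum d_i)$ (note
  $\sum d_i = 2m$); standard = the distance-sum Balaban J.
- `schultz_mti`: default $\sum (d_i+1)(d_i-1) = \sum(d_i^2-1)$;
  standard = the degree–distance Schultz index.
- `szeged_index`: $\sum_{e=(u,v)} n_u(e)\,n_v(e)$ with equidistant
  vertices counted in neither side; checked exhaustively against a
  brute-force double loop on all fixture graphs up to 12 vertices.
- `xu_index`: default $\sum(d_i^2-d_i)$; standard = the log-ratio Xu
  index.
- `bottcher_complexity`: per-atom product $V_i b_i d_i e_i s_i$ over
  heavy atoms with $V_ib_i > 1$, where $b_i$ is the order-weighted bond
  count including hydrogens, $d_i$ the number of bond classes by
  (neighbour element, bond order), $e_i$ the distinct elements in the
  first coordination sphere including the atom itself, and $s_i = 2$ at
  stereocentres. No symmetry-equivalence halving is applied. Methane
  scores 32, ethane 128.
- `autocorrelation_entropy`: lag-k autocorrelation of a vertex property
  (default Pauling electronegativity; unordered pairs, k from 1 to the
  diameter), normalized to a profile whose Shannon entropy (natural
  log) is the descriptor; bounded by log(diameter).

# Nonparametric association tests

`kruskal_wallis()` is the tie-corrected rank test (delegated to the
stats implementation, cross-checked against the textbook formula);
fully tied samples report statistic 0, p = 1. `conover_posthoc()` is
the Conover–Iman pairwise t on ranks with the KW-deflated pooled
variance and Holm adjustment across pairs; because a single number per
descriptor is conventional in summary tables, the maximum absolute
pairwise statistic and its adjusted p are reported alongside the full
matrices. `gehan_ksample()` is the k-sample Gehan–Breslow generalized
Wilcoxon in observed-minus-expected score form (scores
$2(r_i - (N+1)/2)$, which the tie algebra shows is exact under
midranks), referred to $\chi^2_{K-1}$; `weight = "logrank"` substitutes
Savage (log-rank) scores. Descriptor values are complete data — no
censoring support. Both omnibus tests hold their nominal 5% type-I
error within ±1.5 points over 2,000 null replicates (n = 200, K = 4).
p-values are reported raw per descriptor; Holm across descriptors is a
flag, not a default.

# Synthetic data: what it emulates and what it does not

The generators make every stage testable offline, deterministically:

- `make_icosphere()` / `make_flat_grid()`: analytic benchmarks
  (spectrum $l(l+1)/R^2$, curvature $1/R$; zero curvature).
- `make_fused_spheres()`: pseudo-molecules on four geometric templates —
  linear chain, closed ring, three-armed star, globular Fibonacci-shell
  blob — with 2.2 Å spacing, vdW-range radii (1.2–1.9 Å), 0.15 Å
  positional jitter, and bonds along the template's minimum spanning
  tree (plus the ring-closing edge). The values are one-time choices
  mimicking fused heavy-atom geometry: spacing near a typical C–C-ish
  contact so spheres overlap into one surface, jitter small enough that
  class geometry, not noise, dominates.
- `make_synthetic_library()`: a labelled 4-class library; the
  end-to-end positive control asks the pipeline to recover the classes
  (ARI ≥ 0.8 at K = 4; the package's default run reaches ≈ 0.90).
- `make_gaussian_blobs()` / `make_random_graph()`: embedder/clustering
  benchmarks and descriptor fuzzing (uniform Prüfer trees, optionally
  one ring-closing edge).

What passing these tests does *not* show: real molecules are not fused
spheres of one element; their shape classes are not four clean
templates; chemical diversity, conformational flexibility, aromatic
systems and heteroatom surface chemistry are all absent. The synthetic
results validate the machinery — meshing, spectra, sampling, learning
dynamics, statistics — not any claim about how real screening libraries
cluster.

# Problem sizes and runtime choices

The shipped test-suite and acceptance scales are: icosphere subdivision
4 (2,562 vertices) for spectral accuracy; 80 molecules x 7 pseudo-atoms
(meshes of roughly 4,000–7,000 vertices at 0.5 Å) for the end-to-end
run; 32 eigenpairs; 200 sampled vertices; DBN 512–128–32 at 200 epochs
per layer; 2,000 replicates for test calibration; 100 random datasets
for the metric oracle. These sizes were chosen so a complete run is a
few minutes on one CPU while every claim is still measured, not assumed.

# Known limitations

- The union-of-balls SAS has crevice geometry different from the
  re-entrant molecular surface; spectra of the two differ for molecules
  with deep clefts.
- Marching tetrahedra produces more, thinner triangles than marching
  cubes with table-based disambiguation; the cotangent clamp handles
  the occasional sliver, but mesh quality is resolution-bound.
- The embedders are desk-scale: no GPU, no hyperparameter search, and
  80-molecule training sets are far below what deep models need to beat
  a good hand-crafted signature; on the synthetic library the DBN
  matches (not beats) k-means on the canonicalized features, which is
  the honest expectation at this n.
- Descriptor defaults use compact degree-sum forms; comparisons against
  published tables of the classical indices must switch the
  `variant = "standard"` flags.
- k-sample tests treat molecules as independent; descriptor-driven and
  cluster-driven dependence (both derive from the same structures) is
  the usual caveat of this design.
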