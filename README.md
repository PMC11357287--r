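# molspec

Spectral-geometry clustering of small-molecule surfaces in R.

## The problem

Screening libraries hold tens of thousands of small molecules, and most
ways of grouping them lean on fingerprints or predefined distance
metrics that ignore the actual three-dimensional shape of the molecular
surface — the thing a binding pocket or a solvent sees. molspec
implements a shape-first alternative for cheminformatics and
drug-discovery work: represent each molecule by the spectrum of a
differential operator on its solvent-accessible surface, which is
invariant to rotation and translation by construction, then let an
unsupervised neural embedding and k-means find the groups.

## The method

For each molecule:

1. **Surface.** The solvent-accessible surface (SAS) is the zero level
   set of `f(p) = min_i(|p − c_i| − (r_i + r))` over atoms with centres
   `c_i` and Bondi van der Waals radii `r_i`, inflated by a probe of
   radius `r ≈ 1.4 Å` (water). A marching-tetrahedra scan of `f` on a
   regular grid triangulates it into a watertight mesh `(V, E, F)`.
2. **Spectrum.** The cotangent Laplace–Beltrami operator with edge
   weights `w_uv = (cot α + cot β)/2` and barycentric vertex areas
   `A(v)` is assembled, and the `N = 32` smallest eigenpairs of
   `S φ = λ A φ` extracted. The eigenvalues are an isometry-invariant
   shape signature (on a unit sphere they reproduce `l(l+1)` with
   multiplicities `2l+1`); the eigenvectors `Φ = [φ₁|…|φ_N]` carry the
   spatial detail.
3. **Features.** Discrete mean curvature `H(v)` weights an
   Efraimidis–Spirakis reservoir sample of 200 vertices; `Φ` restricted
   to the sample, zero-padded to a fixed 200×N matrix, is the
   molecule's feature matrix.
4. **Embedding + clustering.** A deep belief network (stacked RBMs,
   CD-1) or a convolutional / variational / adversarial autoencoder
   maps the standardized matrices to a 32-dimensional latent space;
   k-means (k-means++, 10 restarts) partitions it at each requested K;
   six validity indices (Calinski–Harabasz, Davies–Bouldin, Dunn, R²,
   silhouette, per-cluster standard deviation) score the partitions.
5. **Descriptor tests.** Six topological descriptors of the
   hydrogen-suppressed molecular graph (a Balaban-style branching
   index, a Schultz-style MTI, the Szeged index, an Xu-style degree
   index, a Böttcher-style complexity, and the Shannon entropy of a
   vertex-property autocorrelation) are tested for association with
   cluster membership by Kruskal–Wallis, Conover–Iman post hoc and
   Gehan–Breslow k-sample tests.

Everything is seeded: one integer reproduces a whole run.

## A worked example

```r
library(molspec)

# a labelled synthetic library: 4 geometric classes x 20 pseudo-molecules
lib <- make_synthetic_library(n_per_class = 20, n_atoms = 7, seed = 1)

cfg <- pipeline_config(model = "dbn", K_values = c(4, 16, 32, 64), seed = 7)
run <- run_pipeline(lib, cfg, output_dir = "run_out")

# how well do the clusters at K = 4 recover the true shape classes?
truth <- as.integer(factor(lib$class))
adjusted_rand_index(run$assignments[["4"]]$labels, truth)
#> [1] 1

run$metrics[, c("K", "calinski_harabasz", "std_deviation", "silhouette")]
#> # A tibble: 4 x 4
#>       K calinski_harabasz std_deviation silhouette
#>   <int>             <dbl>         <dbl>      <dbl>
#> 1     4             2924.     0.259          0.859
#> 2    16         18546379.     0.00118        0.810
#> 3    32        544654375.     0.000120       0.410
#> 4    64       4545787326.     0.0000116      0.147
```

Adjusted Rand index 1 at K = 4 means the latent clustering exactly
recovers the four shape classes. The metric table shows the
characteristic trade-off as K grows: between/within separation
(Calinski–Harabasz) and compactness (standard deviation) improve
monotonically, while the silhouette — which penalizes splitting true
groups — degrades past the natural K.

Individual stages are ordinary functions, pipe-friendly:

```r
mol  <- make_fused_spheres(7, "ring", seed = 3)
mesh <- build_sas_mesh(mol, probe = 1.4, resolution = 0.5)
mesh_stats(mesh)                      # V/E/F, Euler characteristic, area
lap  <- assemble_laplacian(mesh)
sp   <- eigendecompose(lap, N = 32)
tidy(sp)                              # eigenvalue table
autoplot(sp)                          # scree plot
```

A thin CLI over the same functions ships in `inst/cli/molspec`
(subcommands `fixtures`, `mesh`, `spectra`, `features`, `embed`,
`cluster`, `descriptors`, `test`, `run`).

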