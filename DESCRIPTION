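Package: molspec
Title: Spectral-Geometry Clustering of Small-Molecule Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters small molecules by the spectral geometry of their
    solvent-accessible surfaces. Molecules read from SDF, SMILES or PDB are
    triangulated via a signed-distance field and a marching-tetrahedra scan,
    the cotangent Laplace-Beltrami operator is assembled on the mesh and its
    low eigenpairs extracted, curvature-weighted reservoir sampling builds a
    fixed-size spectral feature matrix per molecule, and a family of
    unsupervised embedders (deep belief network, convolutional, variational
    and adversarial autoencoders) reduces those matrices to a latent space
    that is clustered with k-means. Cluster quality is scored with six
    internal validity indices, and nonparametric k-sample tests
    (Kruskal-Wallis, Conover-Iman post hoc, Gehan-Breslow) relate cluster
    membership to six topological descriptors of the hydrogen-suppressed
    molecular graph. Deterministic synthetic fixtures (icospheres, fused-sphere
    pseudo-molecules, random molecular graphs) make the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    methods,
    ggplot2,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    bio3d,
    withr,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
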