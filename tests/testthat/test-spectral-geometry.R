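test_that("cotangent weights match closed-form equilateral values", {
  # two equilateral triangles sharing an edge: w = cot(60)/2 * 2 = 1/sqrt(3)
  h <- sqrt(3) / 2
  mesh <- tri_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, h, 0), c(0.5, -h, 0)),
    rbind(c(1, 2, 3), c(1, 4, 2))
  )
  lap <- assemble_laplacian(mesh)
  w <- lap$edge_weights
  shared <- w$weight[w$from == 1 & w$to == 2]
  expect_equal(shared, 1 / sqrt(3), tolerance = 1e-12)
})

test_that("the operator annihilates constant vectors", {
  mesh <- make_icosphere(1, 2)
  lap <- assemble_laplacian(mesh)
  expect_lt(max(abs(lap$operator %*% rep(1, lap$n))), 1e-10)
})

test_that("barycentric vertex areas partition the mesh area exactly", {
  mesh <- make_icosphere(1, 3)
  lap <- assemble_laplacian(mesh)
  expect_equal(sum(lap$vertex_areas), mesh_stats(mesh)$total_area,
               tolerance = 1e-12)
})

test_that("the weighted operator is symmetric after area scaling", {
  mesh <- make_fused_spheres(3, "linear", seed = 1) |>
    build_sas_mesh(resolution = 0.7)
  lap <- assemble_laplacian(mesh)
  S <- Matrix::Diagonal(lap$n, lap$vertex_areas) %*% lap$operator
  expect_lt(max(abs(S - Matrix::t(S))), 1e-10)
})

test_that("isolated vertices are reported by index", {
  mesh <- structure(
    list(vertices = rbind(diag(3), c(5, 5, 5)), faces = rbind(c(1, 2, 3))),
    class = "tri_mesh"
  )
  expect_error(assemble_laplacian(mesh), "4")
})

test_that("sphere spectrum follows l(l+1) with the right multiplicities", {
  mesh <- make_icosphere(1, 4)
  lap <- assemble_laplacian(mesh)
  sp <- eigendecompose(lap, N = 12)
  expect_lt(sp$values[1], 1e-8)
  expect_equal(sp$values[2:4], rep(2, 3), tolerance = 0.02)
  expect_equal(sp$values[5:9], rep(6, 5), tolerance = 0.03)
  expect_equal(sp$values[10:12], rep(12, 3), tolerance = 0.03)
})

test_that("eigenvectors are A-orthonormal with a deterministic sign", {
  mesh <- make_icosphere(1, 3)
  lap <- assemble_laplacian(mesh)
  sp <- eigendecompose(lap, N = 8)
  G <- t(sp$vectors) %*% (sp$vectors * lap$vertex_areas)
  expect_lt(max(abs(G - diag(8))), 1e-6)
  for (k in 1:8) {
    i <- which.max(abs(sp$vectors[, k]))
    expect_gt(sp$vectors[i, k], 0)
  }
})

test_that("eigenvalues scale as inverse squared length", {
  mesh <- make_icosphere(1, 3)
  sp1 <- eigendecompose(assemble_laplacian(mesh), N = 6)
  sp2 <- eigendecompose(assemble_laplacian(mesh_transform(mesh, scale = 2)),
                        N = 6)
  expect_equal(sp2$values[-1], sp1$values[-1] / 4, tolerance = 1e-6)
})

test_that("the spectrum is invariant under rigid motion", {
  mol <- make_fused_spheres(4, "star", seed = 9)
  mesh <- build_sas_mesh(mol, resolution = 0.6)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- mesh_transform(mesh, rotation = R, translation = c(-4, 2, 7))
  s1 <- eigendecompose(assemble_laplacian(mesh), N = 6)$values
  s2 <- eigendecompose(assemble_laplacian(moved), N = 6)$values
  expect_equal(s2[-1], s1[-1], tolerance = 1e-6)
})

test_that("zero eigenvalue count equals the number of components", {
  mesh <- build_sas_mesh(two_atom_mol(sep = 30), resolution = 0.7)
  expect_equal(mesh_stats(mesh)$n_components, 2)
  sp <- eigendecompose(assemble_laplacian(mesh), N = 4)
  expect_equal(sum(sp$values < 1e-8), 2)
})

test_that("sparse eigenpairs agree with the dense solver", {
  mesh <- make_icosphere(1, 2) # 162 vertices
  lap <- assemble_laplacian(mesh)
  dense <- eigendecompose(lap, N = 10, dense_cutoff = 1e6)
  sparse <- eigendecompose(lap, N = 10, dense_cutoff = 10)
  expect_equal(sparse$values, dense$values, tolerance = 1e-8)
})

test_that("icosphere mean curvature equals 1/R and flat grids are zero", {
  for (R in c(1, 2)) {
    mesh <- make_icosphere(R, 3)
    cv <- mean_curvature(mesh, assemble_laplacian(mesh))
    expect_equal(range(cv$H), rep(1 / R, 2), tolerance = 0.02)
  }
  grid <- make_flat_grid(8, 8)
  expect_warning(cv <- mean_curvature(grid, assemble_laplacian(grid)),
                 "uniform")
  expect_equal(max(cv$H[flat_grid_interior(8, 8)]), 0)
  expect_equal(sum(cv$H_norm), 1, tolerance = 1e-12)
})

test_that("the literal curvature variant is scale-dependent and positive", {
  mesh <- make_icosphere(1, 2)
  lap <- assemble_laplacian(mesh)
  lit <- mean_curvature(mesh, lap, variant = "literal")
  expect_true(all(lit$H > 0))
  big <- mesh_transform(mesh, scale = 2)
  lit2 <- mean_curvature(big, assemble_laplacian(big), variant = "literal")
  expect_gt(mean(lit2$H), mean(lit$H))
})

test_that("an all-flat patch falls back to uniform sampling weights", {
  grid <- make_flat_grid(4, 4)
  expect_warning(cv <- mean_curvature(grid, assemble_laplacian(grid)),
                 "uniform")
  expect_equal(cv$H_norm, rep(1 / 16, 16))
})

test_that("weighted sampling is deterministic and respects edge cases", {
  w <- structure(list(H = c(1, 0, 0), H_norm = c(1, 0, 0)),
                 class = "curvature_field")
  for (s in 1:10) expect_equal(weighted_sample(w, 1, seed = s), 1L)
  w2 <- structure(list(H = runif(7), H_norm = rep(1 / 7, 7)),
                  class = "curvature_field")
  expect_equal(weighted_sample(w2, 10, seed = 1), 1:7)
  expect_identical(weighted_sample(w2, 3, seed = 42),
                   weighted_sample(w2, 3, seed = 42))
})

test_that("first-draw inclusion probabilities follow the weights", {
  w <- structure(list(H = c(0.7, 0.2, 0.1), H_norm = c(0.7, 0.2, 0.1)),
                 class = "curvature_field")
  draws <- vapply(1:20000, function(s) weighted_sample(w, 1, seed = s),
                  integer(1))
  freq <- tabulate(draws, 3) / 20000
  expect_equal(freq, c(0.7, 0.2, 0.1), tolerance = 0.015)
})

test_that("feature matrices are curvature-ordered, padded and relabeling-invariant", {
  mesh <- make_icosphere(1, 2)
  lap <- assemble_laplacian(mesh)
  sp <- eigendecompose(lap, N = 2)
  cv <- mean_curvature(mesh, lap)
  idx <- weighted_sample(cv, 3, seed = 5)
  f <- build_feature_matrix(sp, idx, cv, pad_to = 200)
  expect_equal(dim(f$matrix), c(200, 2))
  expect_equal(f$s, 3)
  expect_true(all(f$matrix[4:200, ] == 0))
  # N = 1 on a connected mesh: constant kernel eigenvector
  f1 <- build_feature_matrix(eigendecompose(lap, N = 1),
                             seq_len(lap$n), cv, pad_to = NULL)
  expect_lt(diff(range(f1$matrix)), 1e-6)
})

test_that("feature matrices are invariant to how the mesh indexes vertices", {
  # a generic mesh with distinct per-vertex curvatures
  mol <- make_fused_spheres(4, "star", seed = 6)
  mesh <- build_sas_mesh(mol, resolution = 0.7)
  lap <- assemble_laplacian(mesh)
  sp <- eigendecompose(lap, N = 3)
  cv <- mean_curvature(mesh, lap)
  n <- nrow(mesh$vertices)
  set.seed(1)
  perm <- sample(n) # perm[i]: new index of old vertex i
  mesh2 <- tri_mesh(mesh$vertices[order(perm), ],
                    matrix(perm[mesh$faces], ncol = 3))
  lap2 <- assemble_laplacian(mesh2)
  sp2 <- eigendecompose(lap2, N = 3)
  cv2 <- mean_curvature(mesh2, lap2)
  expect_equal(cv2$H[perm], cv$H, tolerance = 1e-9)
  sample_old <- order(-cv$H, seq_len(n))[1:20]
  fa <- build_feature_matrix(sp, sample_old, cv, pad_to = NULL)
  fb <- build_feature_matrix(sp2, perm[sample_old], cv2, pad_to = NULL)
  # same physical vertices selected; row order may differ where curvature
  # values tie to numerical noise, so compare each column as a set
  for (k in 1:3) {
    expect_equal(sort(fa$matrix[, k]), sort(fb$matrix[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("duplicate or out-of-range samples are rejected", {
  mesh <- make_icosphere(1, 1)
  lap <- assemble_laplacian(mesh)
  sp <- eigendecompose(lap, N = 2)
  cv <- mean_curvature(mesh, lap)
  expect_error(build_feature_matrix(sp, c(1, 1), cv), "repeated")
  expect_error(build_feature_matrix(sp, c(0, 5), cv), "range")
})
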