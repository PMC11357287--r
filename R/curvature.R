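#' Discrete mean curvature of a mesh
#'
#' Two variants are available. The default, `"normal"`, is the magnitude of
#' the mean-curvature normal: half the norm of the cotangent Laplacian
#' applied to the vertex coordinates, `H(v) = |sum_u w_uv (v - u)| / (2
#' A(v))` with `w_uv = (cot a + cot b)/2`. On a sphere of radius `R` this
#' gives `1/R` at every vertex and exactly zero on planar regions. The
#' `"literal"` variant is the scale-dependent edge-length-weighted cotangent
#' sum `H(v) = sum_u w_uv |v - u|`; it is retained as an alternative
#' curvature weighting but is nonzero even on flat meshes.
#'
#' Curvature values are clamped at zero and normalized to a probability
#' distribution over vertices (`H_norm`), which is also the per-vertex
#' selection probability used by [weighted_sample()]. If the field is
#' identically zero (a flat patch under the `"normal"` variant), uniform
#' weights are substituted with a warning.
#'
#' @param mesh a [tri_mesh()].
#' @param lap the [assemble_laplacian()] of the same mesh.
#' @param variant `"normal"` (default) or `"literal"`.
#' @return An object of class `curvature_field`: list with `H`, `H_norm`,
#'   `selection_prob` and `variant`.
#' @export
mean_curvature <- function(mesh, lap, variant = c("normal", "literal")) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(lap, "cotan_laplacian"))
  variant <- match.arg(variant)
  if (lap$n != nrow(mesh$vertices)) {
    stop("laplacian was assembled on a different mesh")
  }
  if (variant == "normal") {
    # (S V)_i = sum_u w_iu (v_i - v_u): the (unnormalized) mean-curvature
    # normal; its magnitude over 2 A_mixed(v) approximates |H|. The mixed
    # Voronoi area is used here (rather than the barycentric area carried
    # by the Laplacian) because it is markedly more accurate at irregular
    # vertices; both partitions sum to the total mesh area.
    K <- as.matrix(lap$stiffness %*% mesh$vertices)
    H <- sqrt(rowSums(K^2)) / (2 * mixed_vertex_areas(mesh))
    # the mean-curvature normal is undefined on boundary vertices (their
    # one-ring is incomplete); set them to zero so flat patches are
    # exactly zero and boundary artefacts never dominate the sampling
    f <- mesh$faces
    e_all <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
                   f[, c(3, 1), drop = FALSE])
    key <- paste(pmin(e_all[, 1], e_all[, 2]),
                 pmax(e_all[, 1], e_all[, 2]))
    boundary_edges <- names(which(table(key) == 1))
    if (length(boundary_edges) > 0) {
      bverts <- unique(as.integer(unlist(strsplit(boundary_edges, " "))))
      H[bverts] <- 0
    }
  } else {
    ew <- lap$edge_weights
    d <- sqrt(rowSums((mesh$vertices[ew$from, , drop = FALSE] -
                         mesh$vertices[ew$to, , drop = FALSE])^2))
    contrib <- ew$weight * d
    H <- numeric(lap$n)
    for (side in c("from", "to")) {
      acc <- tapply(contrib, ew[[side]], sum)
      idx <- as.integer(names(acc))
      H[idx] <- H[idx] + as.numeric(acc)
    }
  }
  H[H < 0 | !is.finite(H)] <- 0
  if (sum(H) <= 0) {
    warning("curvature field is identically zero; using uniform weights")
    H_norm <- rep(1 / lap$n, lap$n)
  } else {
    H_norm <- H / sum(H)
  }
  structure(
    list(H = H, H_norm = H_norm, selection_prob = H_norm,
         variant = variant),
    class = "curvature_field"
  )
}

# Meyer mixed (Voronoi-style) vertex areas: per triangle, a non-obtuse
# corner gets its circumcentric Voronoi piece (l^2 cot / 8 terms), the
# obtuse corner half the triangle area and the other two a quarter each.
# Partitions the total area exactly, like the barycentric rule, but is far
# more accurate as a curvature normalizer at irregular vertices.
mixed_vertex_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  cot_of <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    dt / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-300)
  }
  cot1 <- cot_of(f[, 1], f[, 2], f[, 3])
  cot2 <- cot_of(f[, 2], f[, 3], f[, 1])
  cot3 <- cot_of(f[, 3], f[, 1], f[, 2])
  l12 <- rowSums((v[f[, 1], , drop = FALSE] - v[f[, 2], , drop = FALSE])^2)
  l23 <- rowSums((v[f[, 2], , drop = FALSE] - v[f[, 3], , drop = FALSE])^2)
  l31 <- rowSums((v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])^2)
  fa <- face_areas(mesh)
  obtuse1 <- cot1 < 0
  obtuse2 <- cot2 < 0
  obtuse3 <- cot3 < 0
  any_obt <- obtuse1 | obtuse2 | obtuse3
  contrib1 <- ifelse(any_obt, ifelse(obtuse1, fa / 2, fa / 4),
                     (l12 * cot3 + l31 * cot2) / 8)
  contrib2 <- ifelse(any_obt, ifelse(obtuse2, fa / 2, fa / 4),
                     (l23 * cot1 + l12 * cot3) / 8)
  contrib3 <- ifelse(any_obt, ifelse(obtuse3, fa / 2, fa / 4),
                     (l31 * cot2 + l23 * cot1) / 8)
  A <- numeric(n)
  for (col in 1:3) {
    contrib <- list(contrib1, contrib2, contrib3)[[col]]
    acc <- tapply(contrib, f[, col], sum)
    idx <- as.integer(names(acc))
    A[idx] <- A[idx] + as.numeric(acc)
  }
  A
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("<curvature_field> %d vertices, variant = %s, H in [%.3g, %.3g]\n",
              length(x$H), x$variant, min(x$H), max(x$H)))
  invisible(x)
}

#' Curvature-weighted sampling without replacement
#'
#' Draws `k` distinct vertex indices with inclusion probabilities driven by
#' the normalized curvature weights, using Efraimidis-Spirakis weighted
#' reservoir sampling: each vertex receives the key `u^(1/w)` with `u ~
#' U(0,1)`, and the `k` largest keys win. The draw is a pure function of
#' `(weights, seed)`. When `k` is at least the number of vertices, all
#' vertices are returned in index order.
#'
#' @param curv a [mean_curvature()] field (or any list with `H_norm`).
#' @param k number of vertices to select.
#' @param seed integer seed.
#' @return Integer vector of `min(k, n)` distinct vertex indices.
#' @export
weighted_sample <- function(curv, k, seed) {
  w <- curv$H_norm
  n <- length(w)
  stopifnot(k >= 1)
  if (k >= n) return(seq_len(n))
  if (sum(w) <= 0) {
    warning("all sampling weights are zero; sampling uniformly")
    w <- rep(1 / n, n)
  }
  u <- local_rng(seed)$runif(n)
  key <- ifelse(w > 0, u^(1 / w), 0)
  order(-key, seq_len(n))[seq_len(k)]
}

#' Spectral feature matrix of a molecule
#'
#' Restricts the eigenvector matrix `Phi = [phi_1 | ... | phi_N]` to the
#' sampled vertices: row `i` holds `(phi_1(v_i), ..., phi_N(v_i))` for the
#' `i`-th sampled vertex. Rows are ordered by descending curvature (ties
#' broken by vertex index), which makes the matrix invariant to how the
#' mesh happens to index its vertices, and the matrix is zero-padded to a
#' fixed number of rows so every molecule yields the same input shape for
#' the embedding models. The near-zero first eigenvector is retained: its
#' (constant) level encodes total surface area through the A-normalization.
#'
#' @param spec a [eigendecompose()] result.
#' @param sample integer vertex indices from [weighted_sample()].
#' @param curv the [mean_curvature()] field used for the sampling.
#' @param molecule_id identifier stored with the matrix.
#' @param pad_to target number of rows (default 200); matrices from meshes
#'   with fewer sampled vertices are zero-padded, and `pad_to = NULL`
#'   disables padding.
#' @return An object of class `spectral_features`: list with `molecule_id`,
#'   `sampled_vertices` (in row order), `matrix` (`pad_to x N`), `s` (the
#'   unpadded row count) and `N`.
#' @export
build_feature_matrix <- function(spec, sample, curv, molecule_id = "mol",
                                 pad_to = 200) {
  stopifnot(inherits(spec, "spectral_decomposition"))
  n <- nrow(spec$vectors)
  sample <- as.integer(sample)
  if (any(sample < 1 | sample > n)) stop("sample index out of range")
  if (anyDuplicated(sample)) stop("repeated vertex in sample")
  ord <- order(-curv$H[sample], sample)
  rows <- sample[ord]
  mat <- spec$vectors[rows, , drop = FALSE]
  s <- length(rows)
  if (!is.null(pad_to)) {
    if (s > pad_to) stop("sample larger than pad_to")
    if (s < pad_to) {
      mat <- rbind(mat, matrix(0, pad_to - s, spec$N))
    }
  }
  structure(
    list(molecule_id = molecule_id, sampled_vertices = rows,
         matrix = mat, s = s, N = spec$N),
    class = "spectral_features"
  )
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features> %s: %d x %d (s = %d)\n",
              x$molecule_id, nrow(x$matrix), x$N, x$s))
  invisible(x)
}

#' Full spectral-feature extraction for one molecule
#'
#' Convenience wrapper chaining [build_sas_mesh()], [assemble_laplacian()],
#' [eigendecompose()], [mean_curvature()], [weighted_sample()] and
#' [build_feature_matrix()] with the package defaults.
#'
#' @inheritParams build_sas_mesh
#' @param n_eigenpairs number of Laplace-Beltrami eigenpairs (default 32).
#' @param sample_size number of curvature-sampled vertices (default 200).
#' @param seed integer seed for the vertex sampling.
#' @param curvature_variant passed to [mean_curvature()].
#' @return A [build_feature_matrix()] result.
#' @export
molecule_features <- function(mol, probe = 1.4, resolution = 0.5,
                              n_eigenpairs = 32, sample_size = 200,
                              seed = 1,
                              curvature_variant = c("normal", "literal")) {
  curvature_variant <- match.arg(curvature_variant)
  mesh <- build_sas_mesh(mol, probe = probe, resolution = resolution)
  lap <- assemble_laplacian(mesh)
  spec <- eigendecompose(lap, N = n_eigenpairs)
  curv <- mean_curvature(mesh, lap, variant = curvature_variant)
  idx <- weighted_sample(curv, k = sample_size, seed = seed)
  build_feature_matrix(spec, idx, curv, molecule_id = mol$id,
                       pad_to = sample_size)
}
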