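#' Assemble the cotangent Laplace-Beltrami operator of a mesh
#'
#' Discretizes the Laplace-Beltrami operator on a triangle mesh with the
#' classical cotangent scheme: each edge `(u, v)` gets weight
#' `w_uv = (cot(alpha) + cot(beta)) / 2`, where `alpha` and `beta` are the
#' angles opposite the edge in its (at most two) incident triangles;
#' boundary edges use the single available angle. Each vertex carries the
#' barycentric area `A(v)`, one third of the summed areas of its incident
#' triangles, so the vertex areas partition the total mesh area exactly.
#' The operator matrix follows the positive semi-definite sign convention:
#' diagonal `sum_k w_ik / A_i`, off-diagonal `-w_ij / A_i`, so its rows
#' annihilate constant vectors and all eigenvalues are nonnegative.
#'
#' @param mesh a [tri_mesh()] with at least one face.
#' @return An object of class `cotan_laplacian` with elements
#'   \describe{
#'     \item{stiffness}{sparse symmetric matrix `S = D - W` of cotangent
#'       weights,}
#'     \item{vertex_areas}{barycentric vertex areas (angstrom^2),}
#'     \item{operator}{the matrix of the operator itself,
#'       `diag(1/A) %*% S`,}
#'     \item{edge_weights}{tibble of edges and their weights `w_uv`.}
#'   }
#' @export
assemble_laplacian <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  v <- mesh$vertices
  if (nrow(f) < 1) stop("mesh has no faces")
  n <- nrow(v)

  incident <- tabulate(as.vector(f), nbins = n)
  if (any(incident == 0)) {
    stop("isolated vertex (no incident face): ",
         paste(utils::head(which(incident == 0), 5), collapse = ", "))
  }

  # per-face corner cotangents: angle at corner a is opposite edge (b, c)
  cot_at <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    dt <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    s <- sqrt(cx^2 + cy^2 + cz^2)
    bad <- s < 1e-12 * pmax(1, abs(dt))
    if (any(bad)) {
      warning("near-degenerate triangle angle; cotangent clamped")
      s[bad] <- pmax(s[bad], abs(dt[bad]) / 1e12, 1e-300)
    }
    dt / s
  }
  cot1 <- cot_at(f[, 1], f[, 2], f[, 3])  # opposite edge (2,3)
  cot2 <- cot_at(f[, 2], f[, 3], f[, 1])  # opposite edge (3,1)
  cot3 <- cot_at(f[, 3], f[, 1], f[, 2])  # opposite edge (1,2)

  ei <- c(f[, 2], f[, 3], f[, 1])
  ej <- c(f[, 3], f[, 1], f[, 2])
  half_cot <- c(cot1, cot2, cot3) / 2

  # symmetric accumulation: each incident triangle contributes cot/2
  W <- Matrix::sparseMatrix(
    i = c(ei, ej), j = c(ej, ei), x = rep(half_cot, 2), dims = c(n, n)
  )
  dg <- Matrix::rowSums(W)
  S <- Matrix::Diagonal(n, dg) - W

  fa <- face_areas(mesh)
  areas <- numeric(n)
  for (col in 1:3) {
    acc <- tapply(rep(fa / 3, 1), f[, col], sum)
    idx <- as.integer(names(acc))
    areas[idx] <- areas[idx] + as.numeric(acc)
  }

  ew <- mesh_edges(mesh)
  edge_weights <- tibble::tibble(
    from = ew[, 1], to = ew[, 2],
    weight = W[cbind(ew[, 1], ew[, 2])]
  )

  structure(
    list(
      stiffness = methods::as(Matrix::forceSymmetric(S), "CsparseMatrix"),
      vertex_areas = areas,
      operator = Matrix::Diagonal(n, 1 / areas) %*% S,
      edge_weights = edge_weights,
      n = n
    ),
    class = "cotan_laplacian"
  )
}

#' @export
print.cotan_laplacian <- function(x, ...) {
  cat(sprintf("<cotan_laplacian> %d vertices, total area %.3f A^2\n",
              x$n, sum(x$vertex_areas)))
  invisible(x)
}

#' Low eigenpairs of the Laplace-Beltrami operator
#'
#' Solves the generalized symmetric eigenproblem `S phi = lambda A phi`
#' (equivalent to the operator `A^-1 S` but numerically symmetric) for the
#' `N` smallest eigenvalues and their `A`-orthonormal eigenvectors. Small
#' problems use a dense solve; larger ones a shift-inverted Lanczos
#' iteration (sparse Cholesky + ARPACK) with a deterministic start vector.
#' Each eigenvector's sign is fixed so its largest-magnitude entry is
#' positive, making the decomposition reproducible across solvers and
#' platforms.
#'
#' Eigenvalues have units of inverse area: scaling the mesh by `s` divides
#' every nonzero eigenvalue by `s^2`. The number of (numerically) zero
#' eigenvalues equals the number of connected surface components.
#'
#' @param lap a [assemble_laplacian()] result.
#' @param N number of eigenpairs (1 to `n_vertices`).
#' @param dense_cutoff below this many vertices a dense solve is used.
#' @return An object of class `spectral_decomposition`: list with
#'   `values` (ascending), `vectors` (n x N, A-orthonormal columns),
#'   `N`, and `vertex_areas`.
#' @export
eigendecompose <- function(lap, N = 32, dense_cutoff = 900) {
  stopifnot(inherits(lap, "cotan_laplacian"))
  n <- lap$n
  if (N < 1 || N > n) stop("N must be between 1 and the number of vertices")
  A <- lap$vertex_areas
  isqa <- 1 / sqrt(A)
  Lsym <- Matrix::Diagonal(n, isqa) %*% lap$stiffness %*%
    Matrix::Diagonal(n, isqa)
  Lsym <- Matrix::forceSymmetric(Lsym)

  if (n <= dense_cutoff || N > n / 4) {
    es <- eigen(as.matrix(Lsym), symmetric = TRUE)
    ord <- order(es$values)
    vals <- es$values[ord][seq_len(N)]
    U <- es$vectors[, ord[seq_len(N)], drop = FALSE]
  } else {
    si <- shift_invert_subspace(Lsym, N)
    vals <- si$values
    U <- si$vectors
  }

  V <- U * isqa  # A-orthonormal generalized eigenvectors
  # deterministic sign: largest-magnitude entry of each column positive
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  structure(
    list(values = vals, vectors = V, N = N, vertex_areas = A),
    class = "spectral_decomposition"
  )
}

# Deterministic shift-inverted blocked subspace iteration for the N
# smallest eigenpairs of a sparse symmetric PSD matrix. A fixed start
# basis, a precomputed sparse Cholesky of the shifted matrix and serial
# dense algebra make reruns bit-identical — unlike ARPACK, whose Lanczos
# workspace introduces run-to-run jitter at the 1e-13 level. A buffer of
# extra basis vectors absorbs eigenvalue clusters; Ritz values are
# monitored for relative convergence.
shift_invert_subspace <- function(Lsym, N, buffer = max(24, N),
                                  tol = 1e-10, max_iter = 200,
                                  solves_per_step = 1) {
  n <- nrow(Lsym)
  q <- min(n, N + buffer)
  scale <- mean(Matrix::diag(Lsym))
  tau <- 1e-6 * scale
  ch <- Matrix::Cholesky(Lsym + Matrix::Diagonal(n, tau), LDL = FALSE,
                         perm = TRUE)
  # deterministic quasi-random start basis
  Q <- matrix(sin(seq_len(n * q) * 0.7531), n, q)
  Q <- qr.Q(qr(Q))
  prev <- rep(Inf, N)
  for (it in seq_len(max_iter)) {
    # one solve per re-orthogonalization: the inverted spectrum is
    # dominated by the near-kernel mode, so stacking solves between QR
    # factorizations would lose the trailing eigendirections
    Z <- as.matrix(Matrix::solve(ch, Q))
    Q <- qr.Q(qr(Z))
    if (it %% 3 == 0 || it == max_iter) {
      Aq <- t(Q) %*% as.matrix(Lsym %*% Q)
      es <- eigen((Aq + t(Aq)) / 2, symmetric = TRUE)
      ritz <- sort(es$values)[seq_len(N)]
      # spectrum-scaled criterion: near-zero kernel eigenvalues only
      # carry numerical noise and cannot meet a per-value relative
      # tolerance
      change <- max(abs(ritz - prev)) / max(abs(ritz), 1e-300)
      if (change < tol || it == max_iter) {
        if (it == max_iter && change >= 1e-8) {
          warning("subspace iteration reached its iteration cap; ",
                  "eigenpairs may be underconverged")
        }
        ord <- order(es$values)[seq_len(N)]
        return(list(values = es$values[ord],
                    vectors = Q %*% es$vectors[, ord, drop = FALSE]))
      }
      prev <- ritz
    }
  }
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("<spectral_decomposition> %d eigenpairs on %d vertices\n",
              x$N, nrow(x$vectors)))
  cat("  eigenvalues:",
      paste(signif(utils::head(x$values, 6), 4), collapse = ", "),
      if (x$N > 6) "..." else "", "\n")
  invisible(x)
}

#' @rdname eigendecompose
#' @param x a `spectral_decomposition`.
#' @param ... unused.
#' @export
tidy.spectral_decomposition <- function(x, ...) {
  tibble::tibble(index = seq_len(x$N), eigenvalue = x$values)
}
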