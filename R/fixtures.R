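#' Icosphere test mesh
#'
#' Builds a geodesic sphere by recursive 4-to-1 subdivision of an
#' icosahedron with projection onto the sphere. The result is a closed
#' genus-0 mesh with `10 * 4^s + 2` vertices at subdivision level `s` —
#' a convenient analytic benchmark: the Laplace-Beltrami spectrum of a
#' radius-`R` sphere is `l(l+1)/R^2` with multiplicity `2l+1`, and its mean
#' curvature is `1/R` everywhere.
#'
#' @param radius sphere radius (angstrom).
#' @param subdivisions integer in 0..6.
#' @return A [tri_mesh()].
#' @examples
#' mesh_stats(make_icosphere(1, 2)) # 162 vertices, 320 faces, chi = 2
#' @export
make_icosphere <- function(radius = 1, subdivisions = 2) {
  stopifnot(radius > 0)
  if (!(subdivisions %in% 0:6)) stop("subdivisions must be in 0..6")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    midpoint <- new.env(hash = TRUE)
    verts <- v
    nv <- nrow(verts)
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint[[key]]
      if (!is.null(idx)) return(idx)
      verts <<- rbind(verts, (verts[a, ] + verts[b, ]) / 2)
      nv <<- nv + 1L
      midpoint[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c); ca <- get_mid(c, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- verts
    f <- newf
  }
  v <- v * radius / sqrt(rowSums(v^2))
  tri_mesh(v, f)
}

#' Flat rectangular grid mesh
#'
#' A planar `nx x ny` vertex grid triangulated with alternating diagonals.
#' Interior vertices of a planar mesh have zero mean curvature, making this
#' the degenerate-curvature fixture.
#'
#' @param nx,ny number of vertices along each side.
#' @param spacing grid spacing (angstrom).
#' @return A [tri_mesh()].
#' @export
make_flat_grid <- function(nx = 10, ny = 10, spacing = 1) {
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  v <- as.matrix(expand.grid(
    x = spacing * (seq_len(nx) - 1),
    y = spacing * (seq_len(ny) - 1)
  ))
  v <- cbind(v, 0)
  idx <- function(i, j) (j - 1L) * nx + i
  f <- matrix(0L, nrow = 2 * (nx - 1) * (ny - 1), ncol = 3)
  r <- 0L
  for (j in seq_len(ny - 1)) {
    for (i in seq_len(nx - 1)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
      f[r + 1L, ] <- c(a, b, c)
      f[r + 2L, ] <- c(a, c, d)
      r <- r + 2L
    }
  }
  tri_mesh(v, f)
}

#' Interior vertices of a flat grid mesh
#'
#' Companion to [make_flat_grid()]: indices of vertices not on the boundary.
#' @inheritParams make_flat_grid
#' @return Integer vector of vertex indices.
#' @export
flat_grid_interior <- function(nx = 10, ny = 10) {
  which(as.vector(outer(seq_len(nx), seq_len(ny),
                        function(i, j) i > 1 & i < nx & j > 1 & j < ny)))
}

#' Fused-sphere pseudo-molecules
#'
#' Generates desk-scale stand-ins for a screening library: pseudo-molecules
#' whose "atoms" are spheres placed on one of four geometric templates,
#' with seeded positional jitter. The templates — linear chain, closed
#' ring, branched star, globular blob — are geometrically distinct by
#' construction, so their solvent-accessible surfaces carry separable
#' spectral signatures. Atom radii are drawn from a typical van der Waals
#' range (1.2 to 1.9 angstrom).
#'
#' @param n_atoms number of pseudo-atoms (>= 1).
#' @param shape_class template: 1 = linear, 2 = ring, 3 = star, 4 = globular,
#'   or one of `"linear"`, `"ring"`, `"star"`, `"globular"`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param spacing centre-to-centre distance between neighbouring
#'   pseudo-atoms (angstrom). Default 2.2, a typical fused-sphere overlap.
#' @param jitter standard deviation of the isotropic positional noise
#'   (angstrom). Default 0.15.
#' @return A [mol_record()] with element set to carbon for every atom (the
#'   geometry, not the chemistry, is the object under study).
#' @export
make_fused_spheres <- function(n_atoms, shape_class, seed,
                               spacing = 2.2, jitter = 0.15) {
  stopifnot(n_atoms >= 1)
  classes <- c("linear", "ring", "star", "globular")
  if (is.numeric(shape_class)) shape_class <- classes[shape_class]
  if (is.na(shape_class) || !shape_class %in% classes) {
    stop("unknown shape class")
  }
  centers <- switch(shape_class,
    linear = cbind(spacing * (seq_len(n_atoms) - 1), 0, 0),
    ring = {
      ang <- 2 * pi * (seq_len(n_atoms) - 1) / n_atoms
      rr <- spacing / (2 * sin(pi / max(n_atoms, 3)))
      cbind(rr * cos(ang), rr * sin(ang), 0)
    },
    star = {
      # central atom plus arms of equal length in trigonal directions
      n_arms <- 3L
      pts <- matrix(0, nrow = 1, ncol = 3)
      dirs <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                    c(-0.5, -sqrt(3) / 2, 0))
      i <- 1L
      while (nrow(pts) < n_atoms) {
        arm <- (i - 1L) %% n_arms + 1L
        step <- (i - 1L) %/% n_arms + 1L
        pts <- rbind(pts, dirs[arm, ] * spacing * step)
        i <- i + 1L
      }
      pts
    },
    globular = {
      # quasi-uniform points in a compact ball (Fibonacci shells)
      n_shell <- ceiling(n_atoms^(1 / 3))
      pts <- matrix(0, nrow = 0, ncol = 3)
      k <- 0L
      while (nrow(pts) < n_atoms) {
        k <- k + 1L
        shell_r <- spacing * 0.62 * k^(1 / 1.5)
        n_on <- min(n_atoms - nrow(pts), max(1L, 2L * k))
        gidx <- seq_len(n_on)
        theta <- acos(1 - 2 * (gidx - 0.5) / n_on)
        phi <- pi * (1 + sqrt(5)) * gidx
        pts <- rbind(pts, cbind(
          shell_r * sin(theta) * cos(phi),
          shell_r * sin(theta) * sin(phi),
          shell_r * cos(theta)
        ))
      }
      pts[seq_len(n_atoms), , drop = FALSE]
    }
  )
  rng <- local_rng(seed)
  centers <- centers + matrix(rng$rnorm(3 * n_atoms, sd = jitter),
                              ncol = 3)
  radii <- rng$runif(n_atoms, 1.2, 1.9)
  # bonds follow the template adjacency (minimum spanning tree of the
  # centre distances, plus the ring-closing edge for the ring class), so
  # the pseudo-molecules also carry a connected heavy-atom graph
  bonds <- NULL
  if (n_atoms >= 2) {
    dmat <- as.matrix(stats::dist(centers))
    g <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                             weighted = TRUE)
    mst <- igraph::mst(g)
    e <- igraph::as_edgelist(mst)
    if (shape_class == "ring" && n_atoms >= 3) {
      have <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      ring_e <- cbind(seq_len(n_atoms), c(seq_len(n_atoms)[-1], 1L))
      ring_e <- cbind(pmin(ring_e[, 1], ring_e[, 2]),
                      pmax(ring_e[, 1], ring_e[, 2]))
      e <- rbind(e, ring_e[!(paste(ring_e[, 1], ring_e[, 2]) %in% have), ,
                           drop = FALSE])
    }
    bonds <- tibble::tibble(from = as.integer(e[, 1]),
                            to = as.integer(e[, 2]), order = 1)
  }
  mol_record(
    id = sprintf("%s_%03d_seed%d", shape_class, n_atoms, seed),
    atoms = tibble::tibble(
      element = rep("C", n_atoms),
      x = centers[, 1], y = centers[, 2], z = centers[, 3],
      vdw_radius = radii
    ),
    bonds = bonds,
    name = shape_class
  )
}

#' Synthetic fused-sphere library with class labels
#'
#' A labelled library of fused-sphere pseudo-molecules spanning the four
#' shape templates, the positive-control input for the end-to-end pipeline:
#' clustering its spectral features should recover the shape classes.
#'
#' @param n_per_class molecules per shape class.
#' @param n_atoms atoms per molecule (single number or length-4 vector, one
#'   per class).
#' @param seed integer seed.
#' @param classes which of the four templates to use (default all).
#' @param ... passed to [make_fused_spheres()].
#' @return A tibble with columns `id`, `class`, `mol` (list-column of
#'   [mol_record()]s).
#' @export
make_synthetic_library <- function(n_per_class = 20, n_atoms = 7, seed = 1,
                                   classes = c("linear", "ring", "star",
                                               "globular"), ...) {
  n_atoms <- rep_len(n_atoms, length(classes))
  rows <- list()
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      mol_seed <- (seed * 1000L + ci * 100L + j) %% .Machine$integer.max
      mol <- make_fused_spheres(n_atoms[ci], classes[ci], seed = mol_seed,
                                ...)
      mol$id <- sprintf("%s_%02d", classes[ci], j)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = mol$id, class = classes[ci], mol = list(mol)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Gaussian blob dataset
#'
#' `K` isotropic unit-variance Gaussians in `dim` dimensions with centroids
#' `separation` standard deviations apart (placed on random orthogonal
#' directions), the standard synthetic benchmark for clustering recovery.
#'
#' @param n total number of points.
#' @param K number of clusters.
#' @param dim dimensionality.
#' @param separation centroid spacing in units of the within-cluster sd.
#' @param seed integer seed.
#' @return List with `x` (n x dim matrix) and `labels` (integer vector).
#' @export
make_gaussian_blobs <- function(n, K, dim = 2, separation = 5, seed = 1) {
  stopifnot(n >= K, K >= 2)
  rng <- local_rng(seed)
  centers <- matrix(rng$rnorm(K * dim), nrow = K)
  # rescale so the minimum pairwise centroid distance equals `separation`
  min_d <- min(stats::dist(centers))
  while (min_d <= 1e-8) {
    centers <- matrix(rng$rnorm(K * dim), nrow = K)
    min_d <- min(stats::dist(centers))
  }
  centers <- centers * (separation / min_d)
  labels <- rep(seq_len(K), length.out = n)
  x <- centers[labels, , drop = FALSE] +
    matrix(rng$rnorm(n * dim), ncol = dim)
  list(x = x, labels = labels)
}

#' Random connected molecular graph
#'
#' Uniform random labelled tree (via Pruefer sequences) or a tree plus one
#' ring-closing edge, with a categorical vertex property drawn from common
#' Pauling electronegativities. Used to fuzz the topological descriptors.
#'
#' @param n number of vertices (>= 2).
#' @param kind `"tree"` or `"ring_tree"`.
#' @param seed integer seed.
#' @return A [molecular_graph()].
#' @export
make_random_graph <- function(n, kind = c("tree", "ring_tree"), seed = 1) {
  stopifnot(n >= 2)
  kind <- match.arg(kind)
  rng <- local_rng(seed)
  if (n == 2) {
    edges <- matrix(c(1L, 2L), ncol = 2)
  } else {
    pruefer <- rng$sample_int(n, n - 2, replace = TRUE)
    edges <- pruefer_to_edges(pruefer, n)
  }
  if (kind == "ring_tree") {
    have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    repeat {
      cand <- sort(rng$sample_int(n, 2))
      if (!(paste(cand[1], cand[2]) %in% have)) break
    }
    edges <- rbind(edges, cand)
  }
  electroneg <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, F = 3.98)
  prop <- as.numeric(electroneg[rng$sample_int(length(electroneg), n,
                                               replace = TRUE)])
  molecular_graph(n = n, edges = edges, vertex_property = prop)
}

# Decode a Pruefer sequence into the edge list of the labelled tree.
# degree[v] = 1 + remaining occurrences of v, so the smallest vertex with
# degree 1 is always the next leaf; removed vertices get degree 0.
pruefer_to_edges <- function(pruefer, n) {
  degree <- rep(1L, n)
  for (p in pruefer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, nrow = n - 1, ncol = 2)
  for (i in seq_along(pruefer)) {
    p <- pruefer[i]
    leaf <- which(degree == 1L)[1L]
    edges[i, ] <- c(leaf, p)
    degree[leaf] <- 0L
    degree[p] <- degree[p] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}
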