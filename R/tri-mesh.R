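#' Triangle mesh container
#'
#' A `tri_mesh` holds the triangulated surface of a molecule: an `n x 3`
#' matrix of vertex coordinates (angstrom) and an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangular face. Edges are derived on
#' demand with [mesh_edges()].
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in
#'   angstrom.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `tri_mesh`.
#' @examples
#' m <- tri_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'   faces = rbind(c(1L, 2L, 3L))
#' )
#' mesh_stats(m)
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must have 3 columns")
  if (nrow(faces) > 0) {
    if (ncol(faces) != 3) stop("faces must have 3 columns")
    if (min(faces) < 1 || max(faces) > nrow(vertices)) {
      stop("face indices out of range")
    }
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen)) stop("degenerate faces (repeated vertex indices)")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  s <- mesh_stats(x)
  cat(sprintf(
    "<tri_mesh> %d vertices, %d edges, %d faces (chi = %d, %d component%s, area %.2f A^2)\n",
    s$n_vertices, s$n_edges, s$n_faces, s$euler_characteristic,
    s$n_components, if (s$n_components == 1) "" else "s", s$total_area
  ))
  invisible(x)
}

#' Undirected edge list of a mesh
#'
#' @param mesh a [tri_mesh()].
#' @return Integer matrix with two columns, each row an unordered vertex pair
#'   (smaller index first), one row per unique edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  e <- rbind(f[, c(1, 2), drop = FALSE],
             f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) == 0) return(numeric(0))
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Summary statistics of a triangle mesh
#'
#' Counts vertices, edges and faces, the Euler characteristic
#' \eqn{\chi = V - E + F}, boundary edges (edges with exactly one incident
#' face), total surface area and the number of edge-connected components.
#'
#' @param mesh a [tri_mesh()].
#' @return A one-row tibble with columns `n_vertices`, `n_edges`, `n_faces`,
#'   `euler_characteristic`, `n_boundary_edges`, `total_area`,
#'   `n_components`.
#' @export
mesh_stats <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  if (nrow(f) == 0) {
    return(tibble::tibble(
      n_vertices = nv, n_edges = 0L, n_faces = 0L,
      euler_characteristic = nv, n_boundary_edges = 0L,
      total_area = 0, n_components = 0L
    ))
  }
  e_all <- rbind(f[, c(1, 2), drop = FALSE],
                 f[, c(2, 3), drop = FALSE],
                 f[, c(3, 1), drop = FALSE])
  e_all <- cbind(pmin(e_all[, 1], e_all[, 2]), pmax(e_all[, 1], e_all[, 2]))
  key <- paste(e_all[, 1], e_all[, 2])
  mult <- table(key)
  ne <- length(mult)
  n_boundary <- sum(mult == 1)

  # components of the surface: vertices never referenced by a face ignored
  used <- sort(unique(as.vector(f)))
  remap <- integer(nv)
  remap[used] <- seq_along(used)
  e_uni <- unique(e_all)
  g <- igraph::make_graph(
    rbind(remap[e_uni[, 1]], remap[e_uni[, 2]]),
    n = length(used), directed = FALSE
  )
  n_comp <- igraph::count_components(g)

  tibble::tibble(
    n_vertices = nv,
    n_edges = as.integer(ne),
    n_faces = nrow(f),
    euler_characteristic = as.integer(nv - ne + nrow(f)),
    n_boundary_edges = as.integer(n_boundary),
    total_area = sum(face_areas(mesh)),
    n_components = as.integer(n_comp)
  )
}

#' Rigidly transform or scale a mesh
#'
#' Utility used throughout the test-suite to check invariance of spectral
#' quantities under rigid motion and their scaling law under dilation.
#'
#' @param mesh a [tri_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric offset.
#' @param scale scalar dilation factor applied before rotation.
#' @return The transformed [tri_mesh()].
#' @export
mesh_transform <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- (mesh$vertices * scale) %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  tri_mesh(v, mesh$faces)
}
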