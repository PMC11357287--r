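#' Molecular graph
#'
#' The hydrogen-suppressed graph view of a molecule: vertices are heavy
#' atoms, edges are bonds, and every vertex carries a numeric property
#' (Pauling electronegativity by default) used by the autocorrelation
#' descriptor. Shortest-path distances use unit edge weights.
#'
#' @param n number of vertices.
#' @param edges integer matrix with two columns (1-based vertex pairs); may
#'   have zero rows only when `n == 1`.
#' @param vertex_property numeric vector of length `n`.
#' @param vertex_element optional character vector of element symbols.
#' @param id identifier carried through error messages and reports.
#' @return An object of class `molecular_graph` with fields `n`, `m`,
#'   `edges`, `degrees`, `dist` (integer shortest-path matrix) and
#'   `vertex_property`.
#' @export
molecular_graph <- function(n, edges, vertex_property = rep(1, n),
                            vertex_element = NULL, id = "graph") {
  stopifnot(n >= 1)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (min(edges) < 1 || max(edges) > n) stop("edge index out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in edge list")
    edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                          pmax(edges[, 1], edges[, 2])))
  }
  g <- igraph::make_graph(rbind(edges[, 1], edges[, 2]), n = n,
                          directed = FALSE)
  if (igraph::count_components(g) > 1) {
    stop("graph '", id, "' is disconnected; ",
         "topological descriptors are defined on connected graphs")
  }
  dist <- igraph::distances(g)
  storage.mode(dist) <- "integer"
  structure(
    list(
      n = as.integer(n), m = nrow(edges), edges = edges,
      degrees = as.integer(igraph::degree(g)),
      dist = dist,
      vertex_property = as.numeric(vertex_property),
      vertex_element = vertex_element,
      id = id
    ),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph> %s: n = %d, m = %d, diameter = %d\n",
              x$id, x$n, x$m, max(x$dist)))
  invisible(x)
}

#' Hydrogen-suppressed graph of a molecule
#'
#' Drops hydrogens, keeps the bonds among heavy atoms, and computes vertex
#' degrees and the breadth-first shortest-path distance matrix. The vertex
#' property defaults to Pauling electronegativity of the element; atomic
#' weight-like alternatives can be supplied as a named vector.
#'
#' @param mol a [mol_record()] with at least one heavy atom and bonds.
#' @param property named numeric vector mapping element symbols to the
#'   per-vertex property.
#' @return A [molecular_graph()].
#' @examples
#' eth <- mol_record(
#'   id = "ethanol",
#'   atoms = tibble::tibble(
#'     element = c("C", "C", "O"),
#'     x = c(0, 1.5, 2.2), y = 0, z = 0
#'   ),
#'   bonds = tibble::tibble(from = c(1, 2), to = c(2, 3), order = 1)
#' )
#' g <- heavy_atom_graph(eth)
#' g$degrees # 1 2 1
#' @export
heavy_atom_graph <- function(mol, property = pauling_electronegativity) {
  stopifnot(inherits(mol, "mol_record"))
  heavy <- which(mol$atoms$element != "H")
  if (length(heavy) == 0) stop("record '", mol$id, "': no heavy atoms")
  remap <- integer(nrow(mol$atoms))
  remap[heavy] <- seq_along(heavy)
  b <- mol$bonds
  keep <- b$from %in% heavy & b$to %in% heavy
  edges <- cbind(remap[b$from[keep]], remap[b$to[keep]])
  el <- mol$atoms$element[heavy]
  unknown <- setdiff(unique(el), names(property))
  if (length(unknown) > 0) {
    stop("record '", mol$id, "': no vertex property for element(s) ",
         paste(unknown, collapse = ", "))
  }
  molecular_graph(
    n = length(heavy), edges = edges,
    vertex_property = unname(property[el]),
    vertex_element = el, id = mol$id
  )
}
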