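#' Topological descriptors of molecular graphs
#'
#' Six descriptors computed on the hydrogen-suppressed molecular graph:
#' a branching index (`balaban_j`), a degree-based connectivity index
#' (`schultz_mti`), the Szeged index, a degree-emphasis index (`xu`), a
#' Boettcher-style per-atom complexity (`complexity`) and the Shannon
#' entropy of the vertex-property autocorrelation (`ac_entropy`).
#'
#' The branching, connectivity and degree-emphasis indices follow compact
#' degree-sum conventions (see the individual functions); the classical
#' literature variants (distance-sum Balaban J, degree-distance Schultz
#' MTI) are available via the `variant` arguments.
#'
#' @name descriptors
NULL

#' Balaban-style branching index
#'
#' Default (`variant = "printed"`): `J = m / (n - 1 + sum(d_i))`, a compact
#' branching ratio of edge count to augmented degree sum (note
#' `sum(d_i) = 2m`, so this equals `m / (n - 1 + 2m)`). The
#' `"standard"` variant computes the classical distance-sum Balaban J,
#' `J = m/(mu + 1) * sum over edges of 1/sqrt(s_u s_v)` with `s_v` the row
#' sum of the distance matrix and `mu = m - n + 1` the cyclomatic number.
#'
#' @param g a [molecular_graph()] with `n >= 2`.
#' @param variant `"printed"` (default) or `"standard"`.
#' @return A single real value.
#' @examples
#' p3 <- molecular_graph(3, rbind(c(1, 2), c(2, 3)))
#' balaban_j(p3) # 2 / (3 - 1 + 4) = 1/3
#' @export
balaban_j <- function(g, variant = c("printed", "standard")) {
  stopifnot(inherits(g, "molecular_graph"))
  variant <- match.arg(variant)
  if (g$n < 2) stop("branching index needs at least 2 vertices")
  if (variant == "printed") {
    g$m / (g$n - 1 + sum(g$degrees))
  } else {
    s <- rowSums(g$dist)
    mu <- g$m - g$n + 1
    terms <- 1 / sqrt(s[g$edges[, 1]] * s[g$edges[, 2]])
    g$m / (mu + 1) * sum(terms)
  }
}

#' Degree-based molecular topological index
#'
#' Default (`variant = "printed"`): `MTI = sum_i (d_i + 1)(d_i - 1)
#' = sum_i (d_i^2 - 1)`. The `"standard"` variant is the classical Schultz
#' index `sum_i d_i (A %*% 1 + D %*% 1)_i = sum_i d_i (d_i + s_i)` with
#' `s_i` the distance-matrix row sum.
#'
#' @inheritParams balaban_j
#' @return A single real value. The one-vertex graph gives -1 under the
#'   printed form (the degenerate `d = 0` case).
#' @export
schultz_mti <- function(g, variant = c("printed", "standard")) {
  stopifnot(inherits(g, "molecular_graph"))
  variant <- match.arg(variant)
  if (variant == "printed") {
    sum((g$degrees + 1) * (g$degrees - 1))
  } else {
    s <- rowSums(g$dist)
    sum(g$degrees * (g$degrees + s))
  }
}

#' Szeged index
#'
#' For every edge `e = (u, v)`, counts the vertices strictly closer to `u`
#' than to `v` (`n_u`) and vice versa (`n_v`); equidistant vertices count
#' in neither. Returns `sum over edges of n_u * n_v`.
#'
#' @param g a [molecular_graph()].
#' @return A single numeric (integer-valued).
#' @examples
#' p4 <- molecular_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' szeged_index(p4) # 1*3 + 2*2 + 3*1 = 10
#' @export
szeged_index <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$m == 0) return(0)
  d <- g$dist
  nu <- colSums(d[, g$edges[, 1], drop = FALSE] <
                  d[, g$edges[, 2], drop = FALSE])
  nv <- colSums(d[, g$edges[, 2], drop = FALSE] <
                  d[, g$edges[, 1], drop = FALSE])
  sum(as.numeric(nu) * as.numeric(nv))
}

#' Degree-emphasis index
#'
#' Default (`variant = "printed"`): `Xu = sum_i (d_i^2 - d_i)`. The
#' `"standard"` variant is the classical Xu index
#' `sqrt(n) * log(sum(d_i s_i^2) / sum(d_i s_i))` with `s_i` the
#' distance-matrix row sums.
#'
#' @inheritParams balaban_j
#' @return A single real value.
#' @export
xu_index <- function(g, variant = c("printed", "standard")) {
  stopifnot(inherits(g, "molecular_graph"))
  variant <- match.arg(variant)
  if (variant == "printed") {
    sum(g$degrees^2 - g$degrees)
  } else {
    s <- rowSums(g$dist)
    sqrt(g$n) * log(sum(g$degrees * s^2) / sum(g$degrees * s))
  }
}

# Per-atom terms of the Boettcher-style complexity, exposed for inspection.
#
# For heavy atom i (hydrogens folded into the environment):
#   V_i valence electrons; b_i order-weighted count of all bonds (including
#   to H); d_i number of bond classes distinguished by (neighbour element,
#   bond order); e_i distinct elements among the atom and its neighbours
#   (including H); s_i = 2 for a stereocentre else 1.
bottcher_terms <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- nrow(atoms)
  heavy <- which(atoms$element != "H")
  nb <- function(i) {
    rows <- bonds$from == i | bonds$to == i
    j <- ifelse(bonds$from[rows] == i, bonds$to[rows], bonds$from[rows])
    tibble::tibble(j = j, order = bonds$order[rows])
  }
  out <- lapply(heavy, function(i) {
    nbrs <- nb(i)
    el <- atoms$element[nbrs$j]
    tibble::tibble(
      atom = i,
      element = atoms$element[i],
      V = atoms$valence_electrons[i],
      b = sum(nbrs$order),
      d = nrow(unique(cbind(el, nbrs$order))),
      e = length(unique(c(atoms$element[i], el))),
      s = ifelse(isTRUE(atoms$is_stereocenter[i]), 2L, 1L)
    )
  })
  dplyr::bind_rows(out)
}

#' Boettcher-style molecular complexity
#'
#' Sums the per-atom product `V_i * b_i * d_i * e_i * s_i` over heavy atoms
#' with `V_i * b_i > 1`: valence electrons, order-weighted bond count
#' (hydrogens included), number of chemically distinct bond classes,
#' number of distinct elements in the atom's first coordination sphere
#' (itself included), and an isomer factor of 2 at stereocentres. The sum
#' runs over all qualifying atoms without symmetry-equivalence halving.
#'
#' @param mol a [mol_record()] with bonds; its heavy-atom graph must be
#'   connected.
#' @return A single real value.
#' @export
bottcher_complexity <- function(mol) {
  stopifnot(inherits(mol, "mol_record"))
  heavy_atom_graph(mol) # connectivity check
  terms <- bottcher_terms(mol)
  keep <- terms$V * terms$b > 1
  sum(terms$V[keep] * terms$b[keep] * terms$d[keep] * terms$e[keep] *
        terms$s[keep])
}

#' Vertex-property autocorrelation and its entropy
#'
#' The graph autocorrelation at lag `k` sums `p(v_i) * p(v_j)` over
#' unordered vertex pairs at shortest-path distance `k`, for `k` from 1 to
#' the graph diameter. The normalized autocorrelation profile
#' `p_k = AC(k) / sum AC` is summarized by its Shannon entropy in natural
#' log units (zero bins contribute nothing; maximum `log(diameter)` for a
#' uniform profile).
#'
#' @param g a [molecular_graph()] with `vertex_property` assigned.
#' @return A list with `ac` (named numeric vector, lags 1..diameter) and
#'   `entropy`.
#' @examples
#' p3 <- molecular_graph(3, rbind(c(1, 2), c(2, 3)),
#'                       vertex_property = c(1, 1, 1))
#' autocorrelation_entropy(p3)$entropy # about 0.6365
#' @export
autocorrelation_entropy <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$n == 1) {
    warning("single-vertex graph: autocorrelation is empty, entropy 0")
    return(list(ac = numeric(0), entropy = 0))
  }
  p <- g$vertex_property
  diam <- max(g$dist)
  pp <- outer(p, p)
  ac <- vapply(seq_len(diam), function(k) {
    sum(pp[g$dist == k]) / 2 # unordered pairs
  }, numeric(1))
  names(ac) <- seq_len(diam)
  tot <- sum(ac)
  if (tot <= 0) {
    warning("all autocorrelation values are zero; entropy 0")
    return(list(ac = ac, entropy = 0))
  }
  pk <- ac / tot
  pos <- pk > 0
  list(ac = ac, entropy = -sum(pk[pos] * log(pk[pos])))
}

#' Descriptor table for a set of molecules
#'
#' Computes all six topological descriptors for each molecule and returns
#' one row per molecule. Molecules whose heavy-atom graph is disconnected
#' (or that lack bonds) raise an error naming the record.
#'
#' @param mols list of [mol_record()]s, or a tibble with a `mol`
#'   list-column as produced by [make_synthetic_library()].
#' @param property named numeric vector for the autocorrelation vertex
#'   property (default Pauling electronegativity).
#' @param balaban,mti,xu variant switches passed through to the individual
#'   descriptor functions.
#' @return A tibble with columns `id`, `balaban_j`, `schultz_mti`,
#'   `szeged`, `xu`, `complexity`, `ac_entropy`.
#' @export
descriptor_table <- function(mols, property = pauling_electronegativity,
                             balaban = "printed", mti = "printed",
                             xu = "printed") {
  if (is.data.frame(mols)) mols <- mols$mol
  if (inherits(mols, "mol_record")) mols <- list(mols)
  if (length(mols) == 0) stop("empty molecule list")
  rows <- lapply(mols, function(mol) {
    g <- heavy_atom_graph(mol, property = property)
    tibble::tibble(
      id = mol$id,
      balaban_j = balaban_j(g, variant = balaban),
      schultz_mti = schultz_mti(g, variant = mti),
      szeged = szeged_index(g),
      xu = xu_index(g, variant = xu),
      complexity = bottcher_complexity(mol),
      ac_entropy = autocorrelation_entropy(g)$entropy
    )
  })
  dplyr::bind_rows(rows)
}

#' Descriptor table for pre-built graphs
#'
#' Like [descriptor_table()] but for [molecular_graph()]s directly (the
#' complexity index needs atoms and bonds, so it is omitted here). Used for
#' synthetic graph libraries.
#'
#' @param graphs list of [molecular_graph()]s.
#' @inheritParams descriptor_table
#' @return A tibble with columns `id`, `balaban_j`, `schultz_mti`,
#'   `szeged`, `xu`, `ac_entropy`.
#' @export
graph_descriptor_table <- function(graphs, balaban = "printed",
                                   mti = "printed", xu = "printed") {
  if (length(graphs) == 0) stop("empty graph list")
  rows <- lapply(graphs, function(g) {
    tibble::tibble(
      id = g$id,
      balaban_j = balaban_j(g, variant = balaban),
      schultz_mti = schultz_mti(g, variant = mti),
      szeged = szeged_index(g),
      xu = xu_index(g, variant = xu),
      ac_entropy = autocorrelation_entropy(g)$entropy
    )
  })
  dplyr::bind_rows(rows)
}
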