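# Shared fixtures built in code at test time.

single_atom_mol <- function(r = 1.7) {
  mol_record(
    id = "atom",
    atoms = tibble::tibble(element = "C", x = 0, y = 0, z = 0,
                           vdw_radius = r)
  )
}

two_atom_mol <- function(sep = 20, r = 1.7) {
  mol_record(
    id = "pair",
    atoms = tibble::tibble(element = c("C", "C"),
                           x = c(-sep / 2, sep / 2), y = 0, z = 0,
                           vdw_radius = r)
  )
}

ethanol_mol <- function() {
  mol_record(
    id = "ethanol",
    atoms = tibble::tibble(
      element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
      x = c(0, 1.52, 2.2, -0.5, -0.5, -0.3, 1.9, 1.9, 3.16),
      y = c(0, 0, 1.2, 0.9, -0.8, -0.2, -0.9, 0.8, 1.2),
      z = c(0, 0, 0, 0.3, 0.4, -1.0, 0.4, 0.5, 0)
    ),
    bonds = tibble::tibble(
      from = c(1, 2, 1, 1, 1, 2, 2, 3),
      to = c(2, 3, 4, 5, 6, 7, 8, 9),
      order = 1
    )
  )
}

# a path graph on n vertices with unit property
path_graph <- function(n, p = rep(1, n)) {
  molecular_graph(n, cbind(seq_len(n - 1), seq_len(n - 1) + 1),
                  vertex_property = p)
}

cycle_graph <- function(n, p = rep(1, n)) {
  molecular_graph(n, cbind(seq_len(n), c(seq_len(n)[-1], 1)),
                  vertex_property = p)
}

star_graph <- function(n_leaves, p = rep(1, n_leaves + 1)) {
  molecular_graph(n_leaves + 1, cbind(rep(1, n_leaves), seq_len(n_leaves) + 1),
                  vertex_property = p)
}

# tetrahedron surface mesh (closed) and single-triangle mesh (open)
tetra_mesh <- function() {
  tri_mesh(
    vertices = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  )
}

triangle_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
}

# brute-force O(n^2) reimplementation of the six validity indices,
# independent of score_clustering (the oracle for the metric tests)
brute_force_metrics <- function(Z, labels) {
  Z <- as.matrix(Z)
  ks <- sort(unique(labels))
  K <- length(ks)
  n <- nrow(Z)
  cent <- t(sapply(ks, function(k) colMeans(Z[labels == k, , drop = FALSE])))
  gmean <- colMeans(Z)
  wcss <- 0
  bcss <- 0
  for (i in seq_len(n)) {
    wcss <- wcss + sum((Z[i, ] - cent[match(labels[i], ks), ])^2)
  }
  for (k in seq_len(K)) {
    bcss <- bcss + sum(labels == ks[k]) * sum((cent[k, ] - gmean)^2)
  }
  tss <- sum(sweep(Z, 2, gmean)^2)
  ch <- (bcss / (K - 1)) / (wcss / (n - K))
  s_i <- sapply(seq_len(K), function(k) {
    idx <- which(labels == ks[k])
    mean(sapply(idx, function(i) sqrt(sum((Z[i, ] - cent[k, ])^2))))
  })
  db_terms <- sapply(seq_len(K), function(i) {
    max(sapply(setdiff(seq_len(K), i), function(j) {
      (s_i[i] + s_i[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }))
  })
  db <- mean(db_terms)
  ed <- function(i, j) sqrt(sum((Z[i, ] - Z[j, ])^2))
  min_between <- Inf
  max_diam <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- ed(i, j)
      if (labels[i] == labels[j]) {
        max_diam <- max(max_diam, d)
      } else {
        min_between <- min(min_between, d)
      }
    }
  }
  dunn <- min_between / max_diam
  r2 <- 1 - wcss / tss
  sil <- mean(sapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) return(0)
    a <- mean(sapply(setdiff(own, i), function(j) ed(i, j)))
    b <- min(sapply(setdiff(ks, labels[i]), function(kk) {
      mean(sapply(which(labels == kk), function(j) ed(i, j)))
    }))
    (b - a) / max(a, b)
  }))
  sdv <- sapply(seq_len(K), function(k) {
    idx <- which(labels == ks[k])
    sqrt(mean(sapply(idx, function(i) sum((Z[i, ] - cent[k, ])^2))))
  })
  std <- sum(table(factor(labels, levels = ks)) * sdv) / n
  tibble::tibble(calinski_harabasz = ch, davies_bouldin = db, dunn = dunn,
                 r_squared = r2, silhouette = sil, std_deviation = std)
}

# textbook Kruskal-Wallis with tie correction, independent of
# stats::kruskal.test
kw_textbook <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  K <- nlevels(groups)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(groups)) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}

# brute-force Szeged index: explicit double loop over edges and vertices
szeged_brute <- function(g) {
  total <- 0
  for (e in seq_len(g$m)) {
    u <- g$edges[e, 1]
    v <- g$edges[e, 2]
    nu <- 0
    nv <- 0
    for (w in seq_len(g$n)) {
      if (g$dist[w, u] < g$dist[w, v]) nu <- nu + 1
      if (g$dist[w, v] < g$dist[w, u]) nv <- nv + 1
    }
    total <- total + nu * nv
  }
  total
}
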