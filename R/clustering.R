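#' k-means clustering of latent representations
#'
#' Lloyd's algorithm with k-means++ seeding, several restarts keeping the
#' lowest within-cluster sum of squares (WCSS), relative convergence
#' tolerance `1e-6`, and empty-cluster repair by reseeding at the point
#' farthest from its centroid. Deterministic given `seed`.
#'
#' @param Z numeric matrix, one row per point (latent coordinates).
#' @param K number of clusters (2 to `nrow(Z)`).
#' @param seed integer seed.
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap per restart.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (1-based integers), `centroids` (K x d), `K`, `wcss`, `seed`.
#' @export
kmeans_fit <- function(Z, K, seed = 1, n_restarts = 10, max_iter = 100) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (K > n) stop("K (", K, ") exceeds the number of points (", n, ")")
  if (K < 2) stop("K must be at least 2")
  rng <- local_rng(seed)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_init(Z, K, rng)
    fit <- lloyd(Z, centers, max_iter = max_iter, rng = rng)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  structure(
    list(labels = best$labels, centroids = best$centers, K = as.integer(K),
         wcss = best$wcss, seed = seed),
    class = "cluster_assignment"
  )
}

kmeanspp_init <- function(Z, K, rng) {
  n <- nrow(Z)
  centers <- matrix(NA_real_, K, ncol(Z))
  first <- rng$sample_int(n, 1)
  centers[1, ] <- Z[first, ]
  d2 <- rowSums(sweep(Z, 2, centers[1, ])^2)
  for (k in seq_len(K - 1) + 1) {
    if (sum(d2) <= 0) {
      pick <- rng$sample_int(n, 1)
    } else {
      pick <- rng$sample_int(n, 1, prob = d2 / sum(d2))
    }
    centers[k, ] <- Z[pick, ]
    d2 <- pmin(d2, rowSums(sweep(Z, 2, centers[k, ])^2))
  }
  centers
}

lloyd <- function(Z, centers, max_iter, rng) {
  n <- nrow(Z)
  K <- nrow(centers)
  zz <- rowSums(Z^2)
  wcss_prev <- Inf
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(zz, rowSums(centers^2), "+") - 2 * Z %*% t(centers)
    d2[d2 < 0] <- 0
    labels <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed at the point farthest from its centroid,
    # never stealing the last member of another cluster
    for (k in which(tabulate(labels, K) == 0)) {
      own_d <- d2[cbind(seq_len(n), labels)]
      sizes <- tabulate(labels, K)
      own_d[sizes[labels] <= 1] <- -Inf
      far <- which.max(own_d)
      if (length(far) == 0 || !is.finite(own_d[far])) break
      centers[k, ] <- Z[far, ]
      labels[far] <- k
      d2[, k] <- rowSums(sweep(Z, 2, centers[k, ])^2)
    }
    for (k in seq_len(K)) {
      if (any(labels == k)) {
        centers[k, ] <- colMeans(Z[labels == k, , drop = FALSE])
      }
    }
    wcss <- sum((Z - centers[labels, , drop = FALSE])^2)
    if (is.finite(wcss_prev) &&
        (wcss_prev - wcss) <= 1e-6 * max(wcss_prev, .Machine$double.eps)) {
      break
    }
    wcss_prev <- wcss
  }
  list(labels = labels, centers = centers,
       wcss = sum((Z - centers[labels, , drop = FALSE])^2))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> K = %d, n = %d, WCSS = %.6g\n",
              x$K, length(x$labels), x$wcss))
  invisible(x)
}

#' @rdname kmeans_fit
#' @param x a `cluster_assignment`.
#' @param ... unused.
#' @export
tidy.cluster_assignment <- function(x, ...) {
  cent <- tibble::as_tibble(x$centroids, .name_repair = ~ paste0("dim", seq_along(.)))
  dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(x$K), size = tabulate(x$labels, x$K)),
    cent
  )
}

#' @rdname kmeans_fit
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble::tibble(K = x$K, n = length(x$labels), wcss = x$wcss,
                 seed = x$seed)
}

#' Six internal cluster-validity indices
#'
#' Scores an assignment with the Calinski-Harabasz variance-ratio
#' criterion, the Davies-Bouldin index, the Dunn index (single-linkage
#' minimum inter-cluster point distance over maximum cluster diameter),
#' R-squared (`1 - WCSS / total sum of squares`), the mean silhouette
#' (singleton clusters score 0), and the size-weighted mean of the
#' per-cluster standard deviation of distances around the cluster mean.
#' All distances are Euclidean.
#'
#' @param Z numeric matrix of points, rows aligned with
#'   `assignment$labels`.
#' @param assignment a [kmeans_fit()] result (or compatible list with
#'   `labels` and `K`).
#' @return A one-row tibble with columns `calinski_harabasz`,
#'   `davies_bouldin`, `dunn`, `r_squared`, `silhouette`, `std_deviation`.
#' @export
score_clustering <- function(Z, assignment) {
  Z <- as.matrix(Z)
  labels <- assignment$labels
  K <- assignment$K
  n <- nrow(Z)
  sizes <- tabulate(labels, K)
  if (any(sizes == 0)) stop("empty cluster in assignment")
  centroids <- do.call(rbind, lapply(seq_len(K), function(k) {
    colMeans(Z[labels == k, , drop = FALSE])
  }))
  overall <- colMeans(Z)

  T_total <- sum(sweep(Z, 2, overall)^2)
  if (T_total <= 0) stop("degenerate data: total sum of squares is zero")
  W_total <- sum((Z - centroids[labels, , drop = FALSE])^2)
  B_total <- sum(sizes * rowSums(sweep(centroids, 2, overall)^2))

  ch <- (B_total / (K - 1)) / (W_total / (n - K))

  # Davies-Bouldin: s_i = mean distance to own centroid
  s <- vapply(seq_len(K), function(k) {
    mean(sqrt(rowSums(sweep(Z[labels == k, , drop = FALSE], 2,
                            centroids[k, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_len(K), function(i) {
    max(vapply(setdiff(seq_len(K), i), function(j) {
      (s[i] + s[j]) / cd[i, j]
    }, numeric(1)))
  }, numeric(1)))

  # Dunn: min inter-cluster point distance over max intra-cluster diameter
  D <- as.matrix(stats::dist(Z))
  diam <- vapply(seq_len(K), function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2) 0 else max(D[idx, idx])
  }, numeric(1))
  min_between <- Inf
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      min_between <- min(min_between,
                         min(D[labels == i, labels == j, drop = FALSE]))
    }
  }
  dunn <- min_between / max(diam)

  r2 <- 1 - W_total / T_total

  sil <- silhouette_mean(D, labels, K, sizes)

  sd_w <- vapply(seq_len(K), function(k) {
    idx <- labels == k
    sqrt(mean(rowSums(sweep(Z[idx, , drop = FALSE], 2,
                            centroids[k, ])^2)))
  }, numeric(1))
  std <- sum(sizes * sd_w) / n

  tibble::tibble(
    calinski_harabasz = ch, davies_bouldin = db, dunn = dunn,
    r_squared = r2, silhouette = sil, std_deviation = std
  )
}

silhouette_mean <- function(D, labels, K, sizes) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels[i]
    if (sizes[k] == 1) {
      s[i] <- 0
      next
    }
    a <- sum(D[i, labels == k]) / (sizes[k] - 1)
    b <- min(vapply(setdiff(seq_len(K), k), function(j) {
      mean(D[i, labels == j])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Metric report across several cluster counts
#'
#' Runs [kmeans_fit()] and [score_clustering()] for each requested `K` and
#' stacks the results, mirroring the usual metrics-by-K report layout.
#'
#' @inheritParams kmeans_fit
#' @param K_values integer vector of cluster counts (default 16, 32, 64).
#' @return A tibble with one row per `K`: `K`, `wcss` and the six metric
#'   columns of [score_clustering()].
#' @export
metric_report <- function(Z, K_values = c(16, 32, 64), seed = 1, ...) {
  rows <- lapply(K_values, function(K) {
    fit <- kmeans_fit(Z, K, seed = seed, ...)
    dplyr::bind_cols(tibble::tibble(K = as.integer(K), wcss = fit$wcss),
                     score_clustering(Z, fit))
  })
  dplyr::bind_rows(rows)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same points;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return A single real value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    # degenerate partitions (all singletons / one cluster): perfect
    # agreement scores 1, anything else 0
    return(as.numeric(sum_ij == max_index))
  }
  (sum_ij - expected) / (max_index - expected)
}
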