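test_that("k-means recovers exact partitions on trivial geometries", {
  sq <- rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10))
  fit <- kmeans_fit(sq, 4, seed = 1)
  expect_equal(fit$wcss, 0)
  expect_equal(length(unique(fit$labels)), 4)

  z <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  fit2 <- kmeans_fit(z, 2, seed = 1)
  expect_equal(sort(fit2$centroids[, 1]), c(0.05, 10.05))
  expect_equal(fit2$wcss, 0.01)
})

test_that("duplicating every point doubles the WCSS at equal centroids", {
  set.seed(11)
  z <- matrix(rnorm(40), ncol = 2)
  f1 <- kmeans_fit(z, 3, seed = 2)
  f2 <- kmeans_fit(rbind(z, z), 3, seed = 2)
  expect_equal(f2$wcss, 2 * f1$wcss, tolerance = 1e-8)
  o1 <- f1$centroids[order(f1$centroids[, 1]), ]
  o2 <- f2$centroids[order(f2$centroids[, 1]), ]
  expect_equal(o1, o2, tolerance = 1e-6)
})

test_that("k-means matches the reference implementation on blobs", {
  blobs <- make_gaussian_blobs(150, 3, dim = 4, separation = 8, seed = 3)
  fit <- kmeans_fit(blobs$x, 3, seed = 5)
  ref <- stats::kmeans(blobs$x, 3, nstart = 10, algorithm = "Lloyd",
                       iter.max = 100)
  expect_equal(fit$wcss, ref$tot.withinss, tolerance = 1e-6)
  expect_equal(adjusted_rand_index(fit$labels, ref$cluster), 1)
})

test_that("stored WCSS matches its recomputation from labels and centroids", {
  blobs <- make_gaussian_blobs(80, 4, dim = 3, separation = 4, seed = 9)
  fit <- kmeans_fit(blobs$x, 4, seed = 1)
  recomputed <- sum((blobs$x - fit$centroids[fit$labels, ])^2)
  expect_equal(fit$wcss, recomputed, tolerance = 1e-8)
  expect_true(all(tabulate(fit$labels, 4) > 0))
})

test_that("K exceeding the number of points is an error", {
  expect_error(kmeans_fit(diag(3), 4, seed = 1), "exceeds")
  expect_error(kmeans_fit(diag(3), 1, seed = 1), "at least 2")
})

test_that("the four-point example reproduces hand-computed metric values", {
  z <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  fit <- kmeans_fit(z, 2, seed = 1)
  m <- score_clustering(z, fit)
  expect_equal(m$calinski_harabasz, 20000, tolerance = 1e-8)
  expect_equal(m$davies_bouldin, 0.01, tolerance = 1e-8)
  expect_equal(m$dunn, 99, tolerance = 1e-8)
  expect_equal(m$r_squared, 1 - 0.01 / 100.01, tolerance = 1e-8)
  expect_equal(m$silhouette, 0.99005, tolerance = 1e-4)
})

test_that("all six metrics agree with the brute-force oracle", {
  for (s in 1:25) {
    rng <- local_rng(s)
    n <- 50
    z <- matrix(rng$rnorm(n * 3), ncol = 3)
    labels <- rng$sample_int(4, n, replace = TRUE)
    while (length(unique(labels)) < 4) {
      labels <- rng$sample_int(4, n, replace = TRUE)
    }
    got <- score_clustering(z, list(labels = labels, K = 4L))
    want <- brute_force_metrics(z, labels)
    for (col in names(want)) {
      expect_equal(got[[col]], want[[col]], tolerance = 1e-8)
    }
  }
})

test_that("singleton partitions give R squared 1 and zero spread", {
  z <- matrix(c(0, 3, 9, 20), ncol = 1)
  got <- score_clustering(z, list(labels = 1:4, K = 4L))
  expect_equal(got$r_squared, 1)
  expect_equal(got$std_deviation, 0)
  expect_equal(got$silhouette, 0) # all-singleton convention
})

test_that("identical points under forced K = 2 are a degenerate error", {
  z <- matrix(rep(1, 10), ncol = 1)
  expect_error(score_clustering(z, list(labels = rep(1:2, 5), K = 2L)),
               "degenerate")
})

test_that("metrics are invariant under rotation and label permutation", {
  blobs <- make_gaussian_blobs(60, 3, dim = 3, separation = 6, seed = 2)
  fit <- kmeans_fit(blobs$x, 3, seed = 1)
  m1 <- score_clustering(blobs$x, fit)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- score_clustering(blobs$x %*% R,
                         list(labels = fit$labels, K = 3L))
  perm <- c(3L, 1L, 2L)
  m3 <- score_clustering(blobs$x,
                         list(labels = perm[fit$labels], K = 3L))
  for (col in names(m1)) {
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-8)
    expect_equal(m3[[col]], m1[[col]], tolerance = 1e-10)
  }
})

test_that("splitting a cluster raises CH and R squared and lowers WCSS", {
  blobs <- make_gaussian_blobs(120, 4, dim = 3, separation = 9, seed = 8)
  f2 <- kmeans_fit(blobs$x, 2, seed = 1)
  f4 <- kmeans_fit(blobs$x, 4, seed = 1)
  m2 <- score_clustering(blobs$x, f2)
  m4 <- score_clustering(blobs$x, f4)
  expect_lt(f4$wcss, f2$wcss)
  expect_gt(m4$calinski_harabasz, m2$calinski_harabasz)
  expect_gt(m4$r_squared, m2$r_squared)
})

test_that("silhouette stays within [-1, 1] under fuzzed inputs", {
  for (s in 1:20) {
    rng <- local_rng(1000 + s)
    n <- 5 + (s %% 20)
    K <- 2 + (s %% 3)
    if (K >= n) next
    z <- matrix(rng$rnorm(n * 2, sd = 0.5 + s / 10), ncol = 2)
    labels <- c(seq_len(K), rng$sample_int(K, n - K, replace = TRUE))
    m <- score_clustering(z, list(labels = labels, K = as.integer(K)))
    expect_gte(m$silhouette, -1)
    expect_lte(m$silhouette, 1)
  }
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(1:4, c(2L, 1L, 4L, 3L)), 1)
  a <- rep(1:2, each = 50)
  set.seed(7)
  b <- sample(rep(1:2, each = 50))
  expect_lt(abs(adjusted_rand_index(a, b)), 0.2)
})

test_that("separation controls blob recoverability", {
  null <- make_gaussian_blobs(200, 4, dim = 2, separation = 0, seed = 4)
  fit0 <- kmeans_fit(null$x, 4, seed = 2)
  expect_lt(abs(adjusted_rand_index(fit0$labels, null$labels)), 0.05)
  strong <- make_gaussian_blobs(400, 4, dim = 2, separation = 10, seed = 4)
  fit1 <- kmeans_fit(strong$x, 4, seed = 2)
  expect_gte(adjusted_rand_index(fit1$labels, strong$labels), 0.99)
})
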