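test_that("Kruskal-Wallis matches the hand-computed two-group value", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
  expect_equal(r$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-10)
  expect_equal(r$df, 1)
})

test_that("fully tied data give statistic 0 and p 1", {
  r <- kruskal_wallis(rep(2.5, 8), rep(1:2, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1)
  g <- gehan_ksample(rep(1, 9), rep(1:3, 3))
  expect_equal(g$statistic, 0)
  expect_equal(g$pvalue, 1)
  co <- conover_posthoc(rep(1, 9), rep(1:3, 3))
  expect_equal(co$summary_pvalue, 1)
})

test_that("KW statistic matches an independent textbook implementation", {
  for (s in 1:100) {
    rng <- local_rng(s)
    n <- 20 + s %% 30
    K <- 2 + s %% 3
    v <- round(rng$rnorm(n), if (s %% 2) 1 else 3) # induce ties half the time
    g <- c(seq_len(K), rng$sample_int(K, n - K, replace = TRUE))
    expect_equal(kruskal_wallis(v, g)$statistic, kw_textbook(v, g),
                 tolerance = 1e-10)
  }
})

test_that("group sizes and labels are validated", {
  expect_error(kruskal_wallis(1:5, rep(1, 5)), "2 groups")
  expect_error(conover_posthoc(1:3, c(1, 1, 1)), "2 groups")
})

test_that("Conover pairwise statistics track the KW separation", {
  rng <- local_rng(42)
  v <- c(rng$rnorm(20), rng$rnorm(20, mean = 10), rng$rnorm(20))
  g <- rep(1:3, each = 20)
  co <- conover_posthoc(v, g)
  # group 2 is shifted by 10 sd: both its pairwise p tiny, other pair large
  expect_lt(co$pvalue[1, 2], 0.01)
  expect_lt(co$pvalue[2, 3], 0.01)
  expect_gt(co$pvalue[1, 3], 0.1)
  expect_equal(co$summary_statistic, max(abs(co$statistic)))
})

test_that("two-group Conover t is monotone in the KW statistic", {
  stats <- sapply(c(0.1, 0.5, 1, 2), function(shift) {
    rng <- local_rng(7)
    v <- c(rng$rnorm(15), rng$rnorm(15, mean = shift))
    g <- rep(1:2, each = 15)
    c(conover_posthoc(v, g)$summary_statistic,
      kruskal_wallis(v, g)$statistic)
  })
  expect_true(all(diff(stats[1, ]) > 0))
  expect_true(all(diff(stats[2, ]) > 0))
})

test_that("Gehan test detects a strong two-sample shift", {
  rng <- local_rng(3)
  v <- c(rng$rnorm(50), rng$rnorm(50, mean = 5))
  g <- rep(1:2, each = 50)
  r <- gehan_ksample(v, g)
  expect_lt(r$pvalue, 0.001)
  # with no censoring and two groups the Gehan statistic is a monotone
  # transform of the Wilcoxon rank sum: compare decisions
  w <- stats::wilcox.test(v[g == 1], v[g == 2])
  expect_lt(w$p.value, 0.001)
})

test_that("Gehan and log-rank variants agree under exchangeability", {
  rng <- local_rng(5)
  v <- rng$rnorm(60)
  g <- rep(1:3, 20)
  a <- gehan_ksample(v, g, weight = "gehan")
  b <- gehan_ksample(v, g, weight = "logrank")
  expect_gt(a$pvalue, 0.05)
  expect_gt(b$pvalue, 0.05)
  expect_equal(a$df, 2)
  expect_equal(b$df, 2)
})

test_that("rank-based tests are invariant under monotone transforms", {
  rng <- local_rng(21)
  v <- abs(rng$rnorm(40)) + 0.1
  g <- rep(1:4, 10)
  for (fn in list(identity, log, sqrt, function(x) x^3)) {
    expect_equal(kruskal_wallis(fn(v), g)$statistic,
                 kruskal_wallis(v, g)$statistic, tolerance = 1e-10)
    expect_equal(gehan_ksample(fn(v), g)$statistic,
                 gehan_ksample(v, g)$statistic, tolerance = 1e-10)
  }
  # and under group relabeling
  perm <- c(3L, 4L, 1L, 2L)
  expect_equal(kruskal_wallis(v, perm[g])$statistic,
               kruskal_wallis(v, g)$statistic)
})

test_that("heavy ties never produce NaN p-values", {
  for (s in 1:20) {
    rng <- local_rng(300 + s)
    v <- rng$sample_int(3, 30, replace = TRUE)
    g <- c(1:3, rng$sample_int(3, 27, replace = TRUE))
    expect_false(is.na(kruskal_wallis(v, g)$pvalue))
    expect_false(is.na(gehan_ksample(v, g)$pvalue))
    expect_false(is.na(conover_posthoc(v, g)$summary_pvalue))
  }
})

test_that("type-I error is calibrated at the nominal level", {
  # 600 null replicates at n = 120, K = 4 keep the unit suite quick; the
  # acceptance suite runs the full 2,000 x n = 200 calibration
  reject_kw <- 0
  reject_ge <- 0
  B <- 600
  for (s in seq_len(B)) {
    rng <- local_rng(5000 + s)
    v <- rng$rnorm(120)
    g <- rep(1:4, 30)
    if (kruskal_wallis(v, g)$pvalue < 0.05) reject_kw <- reject_kw + 1
    if (gehan_ksample(v, g)$pvalue < 0.05) reject_ge <- reject_ge + 1
  }
  expect_lt(abs(reject_kw / B - 0.05), 0.025)
  expect_lt(abs(reject_ge / B - 0.05), 0.025)
})

test_that("test reports detect constructed descriptor-cluster association", {
  graphs <- lapply(1:60, function(s) {
    g <- make_random_graph(6 + s %% 8, "tree", seed = s)
    g$id <- paste0("g", s)
    g
  })
  desc <- graph_descriptor_table(graphs)
  # labels determined by szeged quartiles: positive control
  q <- stats::quantile(desc$szeged, c(0.25, 0.5, 0.75))
  labels <- findInterval(desc$szeged, q) + 1L
  assign_tbl <- tibble::tibble(id = desc$id, K = 4L, cluster = labels)
  rep <- test_report(desc[, c("id", "szeged")], assign_tbl)
  kw_p <- rep$pvalue[rep$test == "kruskal_wallis"]
  expect_lt(kw_p, 1e-6)

  # mismatched ids are an error
  bad <- assign_tbl
  bad$id[1] <- "nonexistent"
  expect_error(test_report(desc[, c("id", "szeged")], bad), "mismatch")
  expect_error(test_report(desc[0, ], assign_tbl), "empty")
})

test_that("null labels give approximately uniform p-values", {
  rng <- local_rng(99)
  pvals <- vapply(1:200, function(b) {
    v <- rng$rnorm(40)
    g <- c(1:4, rng$sample_int(4, 36, replace = TRUE))
    kruskal_wallis(v, g)$pvalue
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
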