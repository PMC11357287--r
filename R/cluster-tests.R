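#' Kruskal-Wallis omnibus test
#'
#' Rank-based k-sample test of location with tie correction; the statistic
#' is referred to a chi-square distribution with `K - 1` degrees of
#' freedom. A fully tied sample (no rank variation) is reported as
#' statistic 0, p-value 1.
#'
#' @param values numeric vector of observations.
#' @param groups group labels aligned with `values` (any type coercible to
#'   factor); every group must be non-empty.
#' @return A list with `statistic`, `pvalue`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_grouping(values, groups)
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, pvalue = 1,
                df = nlevels(groups) - 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), pvalue = kt$p.value,
       df = unname(kt$parameter))
}

check_grouping <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) == 0)) stop("empty group")
  groups
}

#' Conover-Iman post hoc test
#'
#' Pairwise comparisons on the pooled ranks following a Kruskal-Wallis
#' test, using the pooled rank variance deflated by the KW statistic
#' (`t` distributed with `N - K` degrees of freedom under the null).
#' Pairwise p-values are Holm-adjusted across the `K(K-1)/2` pairs. As a
#' single-number summary the maximum absolute pairwise statistic is
#' reported with its adjusted p-value.
#'
#' @inheritParams kruskal_wallis
#' @return A list with `statistic` (matrix of pairwise t values), `pvalue`
#'   (matrix of Holm-adjusted p), `summary_statistic`, `summary_pvalue`.
#' @export
conover_posthoc <- function(values, groups) {
  groups <- check_grouping(values, groups)
  K <- nlevels(groups)
  N <- length(values)
  if (N <= K) stop("need more observations than groups")
  r <- rank(values)
  n_g <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  H <- kruskal_wallis(values, groups)$statistic
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  if (S2 <= 0) {
    # fully tied data: no separation anywhere
    tmat <- matrix(0, K, K)
    pmat <- matrix(1, K, K)
    diag(pmat) <- NA_real_
    return(list(statistic = tmat, pvalue = pmat,
                summary_statistic = 0, summary_pvalue = 1))
  }
  scale2 <- S2 * (N - 1 - H) / (N - K)
  scale2 <- max(scale2, .Machine$double.eps)
  tmat <- matrix(0, K, K, dimnames = list(levels(groups), levels(groups)))
  praw <- matrix(NA_real_, K, K, dimnames = dimnames(tmat))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      se <- sqrt(scale2 * (1 / n_g[i] + 1 / n_g[j]))
      tt <- (rbar[i] - rbar[j]) / se
      tmat[i, j] <- tmat[j, i] <- tt
      praw[i, j] <- praw[j, i] <- 2 * stats::pt(-abs(tt), df = N - K)
    }
  }
  upper <- praw[upper.tri(praw)]
  adj <- stats::p.adjust(upper, method = "holm")
  pmat <- praw
  pmat[upper.tri(pmat)] <- adj
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  imax <- which.max(abs(tmat[upper.tri(tmat)]))
  list(
    statistic = tmat, pvalue = pmat,
    summary_statistic = abs(tmat[upper.tri(tmat)])[imax],
    summary_pvalue = adj[imax]
  )
}

#' Gehan-Breslow generalized Wilcoxon k-sample test
#'
#' Nonparametric k-sample test built on Gehan scores: each observation
#' scores the number of observations it exceeds minus the number exceeding
#' it (ties score zero; with complete, uncensored data this is a
#' Wilcoxon-type comparison). With group score sums `S_g`, the statistic
#' `(N - 1) * sum_g(S_g^2 / n_g) / sum_i(a_i^2)` is referred to chi-square
#' with `K - 1` degrees of freedom. `weight = "logrank"` substitutes
#' log-rank scores (each observation's cumulative hazard contribution),
#' the unweighted variant of the same family.
#'
#' @inheritParams kruskal_wallis
#' @param weight `"gehan"` (default) or `"logrank"`.
#' @return A list with `statistic`, `pvalue`, `df`.
#' @export
gehan_ksample <- function(values, groups, weight = c("gehan", "logrank")) {
  groups <- check_grouping(values, groups)
  weight <- match.arg(weight)
  K <- nlevels(groups)
  N <- length(values)
  if (weight == "gehan") {
    r <- rank(values)
    # Gehan score = (#less) - (#greater) = 2*(rank - (N+1)/2) under ties
    a <- 2 * (r - (N + 1) / 2)
  } else {
    # log-rank scores for uncensored data: sum of 1/n_at_risk up to the
    # observation minus 1 (Savage scores, centred)
    ord <- order(values)
    n_risk <- N - rank(values, ties.method = "min") + 1
    # cumulative hazard at each distinct value
    uv <- sort(unique(values))
    dcount <- as.numeric(table(values)[as.character(uv)])
    atrisk <- N - cumsum(c(0, utils::head(dcount, -1)))
    haz <- cumsum(dcount / atrisk)
    a <- haz[match(values, uv)] - 1
  }
  denom <- sum(a^2)
  if (denom <= 0) {
    return(list(statistic = 0, pvalue = 1, df = K - 1))
  }
  S_g <- tapply(a, groups, sum)
  n_g <- tabulate(groups)
  stat <- (N - 1) * sum(S_g^2 / n_g) / denom
  list(statistic = unname(stat),
       pvalue = stats::pchisq(stat, df = K - 1, lower.tail = FALSE),
       df = K - 1)
}

#' Nonparametric test report: descriptors against cluster membership
#'
#' For each descriptor column and each clustering, runs the Kruskal-Wallis
#' omnibus test, the Conover-Iman post hoc summary, and the Gehan-Breslow
#' k-sample test, and stacks the results in a long table (one row per
#' descriptor x K x test).
#'
#' @param descriptors a [descriptor_table()] result (tibble with an `id`
#'   column and numeric descriptor columns).
#' @param assignments tibble with columns `id`, `K`, `cluster`: the
#'   cluster label of each molecule at each cluster count. Ids must match
#'   the descriptor table exactly; mismatches raise an error listing them.
#' @return A tibble with columns `K`, `descriptor`, `test`, `statistic`,
#'   `pvalue`.
#' @export
test_report <- function(descriptors, assignments) {
  if (nrow(descriptors) == 0) stop("empty descriptor table")
  desc_cols <- setdiff(names(descriptors), "id")
  for (Kv in unique(assignments$K)) {
    ids_k <- assignments$id[assignments$K == Kv]
    missing <- setdiff(descriptors$id, ids_k)
    extra <- setdiff(ids_k, descriptors$id)
    if (length(missing) > 0 || length(extra) > 0) {
      stop("descriptor/assignment id mismatch at K = ", Kv, ": ",
           paste(utils::head(c(missing, extra), 10), collapse = ", "))
    }
  }
  rows <- list()
  for (Kv in sort(unique(assignments$K))) {
    sub <- assignments[assignments$K == Kv, ]
    labels <- sub$cluster[match(descriptors$id, sub$id)]
    for (dc in desc_cols) {
      v <- descriptors[[dc]]
      kw <- kruskal_wallis(v, labels)
      co <- conover_posthoc(v, labels)
      ge <- gehan_ksample(v, labels)
      rows[[length(rows) + 1]] <- tibble::tibble(
        K = Kv, descriptor = dc,
        test = c("kruskal_wallis", "conover", "gehan"),
        statistic = c(kw$statistic, co$summary_statistic, ge$statistic),
        pvalue = c(kw$pvalue, co$summary_pvalue, ge$pvalue)
      )
    }
  }
  dplyr::bind_rows(rows)
}
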