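# Chi-squared inference for ranking data: tests of uniformity built from
# mean ranks, pair proportions or marginal frequencies, and a two-sample
# comparison test between ranking datasets.
#
# Under uniformity over S_k the mean rank of every item is (k+1)/2, every
# pair proportion is 1/2 and every marginal proportion is 1/k. The three
# statistics below are the classical quadratic forms in these deviations,
# scaled by the exact covariance structure of a uniform random permutation
# so that each is asymptotically chi-squared with the stated degrees of
# freedom: k - 1 (mean rank), choose(k, 2) (pairs), (k - 1)^2 (marginals).

new_rank_test <- function(statistic, df, basis, method, data.name) {
  structure(
    list(statistic = c("X-squared" = statistic),
         parameter = c(df = df),
         p.value = stats::pchisq(statistic, df, lower.tail = FALSE),
         method = method, data.name = data.name, basis = basis),
    class = c("rank_test", "htest")
  )
}

#' Chi-squared tests of uniformity for ranking data
#'
#' Tests the null hypothesis that all `k!` rankings are equally likely.
#' Three summary bases avoid the sparse `k!`-cell table:
#'
#' * `"mean_rank"`: `(12N / (k(k+1))) * sum_j (m_j - (k+1)/2)^2`,
#'   df `k - 1` (the Friedman-type statistic);
#' * `"pairs"`: `12N * [ sum_{s>t} (P_st/N - 1/2)^2 -
#'   (1/(k+1)) * sum_j (m_j - (k+1)/2)^2 ]`, df `choose(k, 2)`;
#' * `"marginals"`: `N(k-1) * sum_{s,t} (M_st/N - 1/k)^2`, df `(k-1)^2`;
#' * `"rankings"`: the plain chi-squared statistic over all `k!` cells with
#'   expected count `N / k!`; refused when that expected count is below 5,
#'   because the chi-squared approximation is then unreliable.
#'
#' @param x individual or aggregated ranking table (complete rankings).
#' @param basis which summary the statistic is built from.
#' @return a `rank_test` object (inherits from `htest`).
#' @examples
#' set.seed(1)
#' test_uniform(sample_luce(c(4, 2, 1), 100), basis = "mean_rank")
#' @export
test_uniform <- function(x, basis = c("mean_rank", "pairs", "marginals",
                                      "rankings")) {
  basis <- match.arg(basis)
  dn <- deparse(substitute(x))
  p <- rt_parts(x, allow_ties = FALSE)
  k <- p$k
  N <- p$N
  if (basis == "rankings") {
    if (N / factorial(k) < 5) {
      stop("expected count per ranking is N/k! = ",
           signif(N / factorial(k), 3),
           " < 5; the chi-squared approximation over all rankings is ",
           "unreliable -- use basis = 'mean_rank', 'pairs' or 'marginals'")
    }
    counts <- ranking_counts(p)
    E <- N / factorial(k)
    stat <- sum((counts - E)^2 / E)
    return(new_rank_test(stat, factorial(k) - 1, basis,
                         "Chi-squared test of uniformity (all rankings)", dn))
  }
  d <- destat_parts(p)
  mdev <- d$mean_rank - (k + 1) / 2
  stat <- switch(
    basis,
    mean_rank = 12 * N / (k * (k + 1)) * sum(mdev^2),
    pairs = {
      Plow <- d$pair[lower.tri(d$pair)] # entries (s, t) with s > t
      12 * N * (sum((Plow / N - 0.5)^2) - sum(mdev^2) / (k + 1))
    },
    marginals = N * (k - 1) * sum((d$marginal / N - 1 / k)^2)
  )
  df <- switch(basis,
               mean_rank = k - 1,
               pairs = choose(k, 2),
               marginals = (k - 1)^2)
  new_rank_test(stat, df, basis,
                paste0("Chi-squared test of uniformity (", basis, ")"), dn)
}

# descriptives without the user-facing validation round trip
destat_parts <- function(p) {
  k <- p$k
  mean_rank <- colSums(p$R * p$freq) / p$N
  pair <- matrix(0, k, k)
  marginal <- matrix(0, k, k)
  for (s in seq_len(k)) {
    for (t in seq_len(k)) {
      if (s != t) pair[s, t] <- sum(p$freq[p$R[, s] > p$R[, t]])
      marginal[s, t] <- sum(p$freq[p$R[, s] == t])
    }
  }
  list(mean_rank = mean_rank, pair = pair, marginal = marginal)
}

# observed frequency of every ranking in S_k, in permutations_of() row order
ranking_counts <- function(p) {
  perms <- permutations_of(p$k)
  key <- function(m) apply(m, 1L, paste, collapse = ",")
  idx <- match(key(p$R), key(perms))
  counts <- numeric(nrow(perms))
  agg <- rowsum(p$freq, idx)
  counts[as.integer(rownames(agg))] <- agg[, 1L]
  counts
}

#' Compare two ranking datasets
#'
#' Tests whether two sets of rankings of the same `k` items share a common
#' preference structure, via the standard two-sample chi-squared
#' contingency test applied to a chosen summary of each dataset:
#'
#' * `"mean_rank"`: the `2 x k` table of per-item rank sums;
#' * `"pairs"`: the pair matrices flattened to `choose(k, 2)` cells;
#' * `"marginals"`: the marginal matrices flattened to `k^2` cells.
#'
#' Degrees of freedom are `q - 1` for `q` retained cells. Cells empty in
#' both datasets carry no information and are dropped (with a warning by
#' default), reducing the degrees of freedom accordingly.
#'
#' @param a,b individual or aggregated ranking tables over the same items.
#' @param basis summary used for the comparison.
#' @param zero_cells `"drop"` removes cells empty in both datasets with a
#'   warning; `"error"` refuses them.
#' @return a `rank_test` object.
#' @export
compare_rankings <- function(a, b, basis = c("pairs", "marginals", "mean_rank"),
                             zero_cells = c("drop", "error")) {
  basis <- match.arg(basis)
  zero_cells <- match.arg(zero_cells)
  dn <- paste(deparse(substitute(a)), "vs", deparse(substitute(b)))
  pa <- rt_parts(a, allow_ties = FALSE)
  pb <- rt_parts(b, allow_ties = FALSE)
  if (pa$k != pb$k) stop("datasets rank different numbers of items")
  row_of <- function(p) {
    d <- destat_parts(p)
    switch(basis,
           mean_rank = colSums(p$R * p$freq), # rank sums per item
           pairs = d$pair[lower.tri(d$pair)],
           marginals = as.vector(d$marginal))
  }
  tab <- rbind(row_of(pa), row_of(pb))
  empty <- colSums(tab) == 0
  if (any(empty)) {
    if (zero_cells == "error") {
      stop(sum(empty), " cell(s) are empty in both datasets")
    }
    warning(sum(empty), " cell(s) empty in both datasets were dropped; ",
            "degrees of freedom reduced accordingly")
    tab <- tab[, !empty, drop = FALSE]
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  new_rank_test(stat, ncol(tab) - 1L, basis,
                paste0("Chi-squared comparison of two ranking datasets (",
                       basis, ")"), dn)
}

#' @exportS3Method generics::tidy
tidy.rank_test <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic),
                 df = unname(x$parameter),
                 p.value = x$p.value,
                 basis = x$basis,
                 method = x$method)
}

#' @exportS3Method generics::glance
glance.rank_test <- function(x, ...) tidy(x)
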