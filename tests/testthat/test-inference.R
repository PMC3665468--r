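# Uniformity tests and the two-sample comparison test.

test_that("uniformity statistics match hand-computed values on {(1,2,3): 2}", {
  tab <- tiny_table()
  t1 <- test_uniform(tab, "mean_rank")
  expect_equal(unname(t1$statistic), 4)
  expect_equal(unname(t1$parameter), 2)
  t2 <- test_uniform(tab, "pairs")
  expect_equal(unname(t2$statistic), 6)
  expect_equal(unname(t2$parameter), 3)
  t3 <- test_uniform(tab, "marginals")
  expect_equal(unname(t3$statistic), 8)
  expect_equal(unname(t3$parameter), 4)
  expect_equal(t1$p.value,
               pchisq(4, 2, lower.tail = FALSE))
})

test_that("stated degrees of freedom scale with k", {
  tab7 <- rank_agg(random_rankings(7, 50, seed = 1))
  expect_equal(unname(test_uniform(tab7, "mean_rank")$parameter), 6)
  expect_equal(unname(test_uniform(tab7, "pairs")$parameter), 21)
  expect_equal(unname(test_uniform(tab7, "marginals")$parameter), 36)
})

test_that("perfectly balanced tables give zero statistics", {
  tab <- balanced_table(4, freq = 2)
  for (b in c("mean_rank", "pairs", "marginals")) {
    expect_equal(unname(test_uniform(tab, b)$statistic), 0)
  }
})

test_that("the pairs statistic is a nonnegative quadratic form", {
  set.seed(202)
  for (r in 1:1000) {
    tab <- rank_agg(random_rankings(4, sample(10:60, 1)))
    expect_gte(unname(test_uniform(tab, "pairs")$statistic), -1e-10)
  }
})

test_that("pairs statistic equals the generalized-inverse covariance oracle", {
  for (k in 4:5) {
    perms <- permutations_of(k)
    pr <- which(upper.tri(diag(k)), arr.ind = TRUE)
    Y <- sapply(seq_len(nrow(pr)), function(p) {
      as.numeric(perms[, pr[p, 2]] > perms[, pr[p, 1]])
    })
    Sig <- stats::cov(Y) * (nrow(Y) - 1) / nrow(Y) # exact uniform covariance
    Sig_pinv <- MASS::ginv(Sig)
    set.seed(77 + k)
    for (r in 1:50) {
      n <- 40
      idx <- sample(nrow(perms), n, replace = TRUE)
      tab <- rank_agg(as.data.frame(perms[idx, , drop = FALSE]))
      phat <- colMeans(Y[idx, , drop = FALSE])
      oracle <- n * drop(t(phat - 0.5) %*% Sig_pinv %*% (phat - 0.5))
      expect_equal(unname(test_uniform(tab, "pairs")$statistic), oracle,
                   tolerance = 1e-8)
    }
  }
})

test_that("all statistics are invariant under item relabeling", {
  ind <- random_rankings(4, 120, seed = 5)
  rel <- ind[, c(3, 1, 4, 2)]
  names(rel) <- names(ind)
  for (b in c("mean_rank", "pairs", "marginals")) {
    expect_equal(unname(test_uniform(ind, b)$statistic),
                 unname(test_uniform(rel, b)$statistic))
  }
})

test_that("the all-rankings test is guarded against sparse cells", {
  expect_error(test_uniform(random_rankings(4, 30, seed = 2), "rankings"),
               "< 5")
  tab <- rank_agg(random_rankings(3, 60, seed = 2))
  t <- test_uniform(tab, "rankings")
  expect_equal(unname(t$parameter), 5)
  expect_gte(unname(t$statistic), 0)
})

test_that("comparing a dataset with itself gives a zero statistic", {
  tab <- rank_agg(random_rankings(4, 100, seed = 9))
  for (b in c("pairs", "marginals", "mean_rank")) {
    tr <- compare_rankings(tab, tab, basis = b)
    expect_equal(unname(tr$statistic), 0)
    expect_equal(tr$p.value, 1)
  }
})

test_that("the marginals comparison uses k^2 flattened cells", {
  a <- rank_agg(random_rankings(7, 200, seed = 3))
  b <- rank_agg(random_rankings(7, 200, seed = 4))
  tr <- compare_rankings(a, b, basis = "marginals")
  expect_equal(unname(tr$parameter), 48) # 49 cells, contingency df q - 1
  expect_error(compare_rankings(a, rank_agg(random_rankings(4, 50, seed = 1))),
               "different numbers of items")
})

test_that("the comparison test is valid (never anti-conservative) under the null", {
  # The contingency chi-squared treats the flattened summary cells as
  # multinomial counts; a judge's cells are dependent, which makes the
  # test conservative. Validity means the type-I error does not exceed
  # the nominal level (up to Monte-Carlo noise), and power against a
  # genuinely different model is still high.
  set.seed(404)
  reps <- 400
  rej_null <- 0
  rej_alt <- 0
  for (r in seq_len(reps)) {
    a <- sample_dbm(80, pi0 = 1:4, lambda = 0.5)
    b <- sample_dbm(80, pi0 = 1:4, lambda = 0.5)
    c_ <- sample_dbm(80, pi0 = 4:1, lambda = 0.5)
    rej_null <- rej_null +
      (compare_rankings(a, b, basis = "marginals")$p.value < 0.05)
    rej_alt <- rej_alt +
      (compare_rankings(a, c_, basis = "marginals")$p.value < 0.05)
  }
  expect_lte(rej_null / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(rej_alt / reps, 0.99)
})

test_that("test results tidy into one-row tibbles", {
  tr <- test_uniform(tiny_table(), "mean_rank")
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$statistic, 4)
  expect_equal(td$basis, "mean_rank")
})
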