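# Core data model: aggregation, ranking/ordering conversion, imputation,
# descriptive statistics.

test_that("rank_agg counts identical rows and orders output lexicographically", {
  ind <- data.frame(a = c(1, 1, 2), b = c(2, 2, 1), c = c(3, 3, 3))
  tab <- rank_agg(ind)
  expect_equal(names(tab), c("a", "b", "c", "n"))
  expect_equal(tab$n, c(2, 1))
  expect_equal(unlist(tab[1, 1:3], use.names = FALSE), c(1, 2, 3))
  expect_equal(sum(tab$n), nrow(ind))

  six <- as.data.frame(permutations_of(3))
  tab6 <- rank_agg(six)
  expect_equal(nrow(tab6), 6)
  expect_true(all(tab6$n == 1))
  expect_equal(sum(tab6$n), 6)
})

test_that("rank_agg validates its input", {
  expect_error(rank_agg(data.frame(a = numeric(0), b = numeric(0))),
               "no rankings")
  expect_error(rank_agg(data.frame(a = 1, b = 1)), "permutation")
  # imputed ties pass only when flagged
  tied <- data.frame(a = 1, b = 2.5, c = 2.5)
  expect_error(rank_agg(tied), "permutation")
  expect_equal(rank_agg(tied, allow_ties = TRUE)$n, 1)
})

test_that("aggregation conserves the judge count on random inputs", {
  for (k in 3:5) {
    ind <- random_rankings(k, 200, seed = k)
    expect_equal(sum(rank_agg(ind)$n), 200)
  }
})

test_that("ranking/ordering conversion inverts correctly", {
  expect_equal(ranking_to_ordering(c(2, 3, 1)), c(3, 1, 2))
  expect_equal(ranking_to_ordering(1:5), 1:5)
  expect_error(ranking_to_ordering(c(1, 2.5, 2.5)), "ties")
  # round trip over all of S_4, both directions
  perms <- permutations_of(4)
  for (i in seq_len(nrow(perms))) {
    expect_equal(ordering_to_ranking(ranking_to_ordering(perms[i, ])),
                 perms[i, ])
    expect_equal(ranking_to_ordering(ordering_to_ranking(perms[i, ])),
                 perms[i, ])
  }
})

test_that("partial rankings are imputed with the mean unassigned rank", {
  expect_equal(impute_partial(c(1, 2, 3, 4, 5, NA, NA)),
               c(1, 2, 3, 4, 5, 6.5, 6.5))
  expect_equal(impute_partial(c(1, NA, NA)), c(1, 2.5, 2.5))
  expect_equal(impute_partial(c(2, 1, 3)), c(2, 1, 3)) # nothing to do
  expect_error(impute_partial(c(2, 3, NA)), "prefix")
  k <- 7
  out <- impute_partial(c(3, 1, NA, 2, NA, NA, NA))
  expect_equal(sum(out), k * (k + 1) / 2)
})

test_that("destat reproduces the single-ranking and enumeration cases", {
  d <- destat(tiny_table())
  expect_equal(unname(d$mean_rank), c(1, 2, 3))
  expect_equal(d$pair["b", "a"], 2)
  expect_equal(d$pair["a", "b"], 0)
  expect_equal(unname(d$marginal), 2 * diag(3))

  db <- destat(balanced_table(3))
  expect_equal(unname(db$mean_rank), rep(2, 3))
  expect_true(all(db$pair[row(db$pair) != col(db$pair)] == 3))
  expect_true(all(db$marginal == 2))
})

test_that("destat invariants hold on random complete-ranking tables", {
  for (k in c(3, 5)) {
    ind <- random_rankings(k, 150, seed = 10 + k)
    d <- destat(ind)
    n <- nrow(ind)
    expect_equal(sum(d$mean_rank), k * (k + 1) / 2)
    off <- row(d$pair) != col(d$pair)
    expect_true(all((d$pair + t(d$pair))[off] == n))
    expect_true(all(diag(d$pair) == 0))
    expect_equal(unname(rowSums(d$marginal)), rep(n, k))
    expect_equal(unname(colSums(d$marginal)), rep(n, k))
    # aggregated table gives identical descriptives
    da <- destat(rank_agg(ind))
    expect_equal(unname(da$mean_rank), unname(d$mean_rank))
    expect_equal(unname(da$pair), unname(d$pair))
    expect_equal(unname(da$marginal), unname(d$marginal))
  }
})

test_that("relabeling items permutes the descriptives consistently", {
  ind <- random_rankings(4, 80, seed = 4)
  gam <- c(3, 1, 4, 2) # new position of each item
  rel <- ind[, gam]
  names(rel) <- names(ind)
  d0 <- destat(ind)
  d1 <- destat(rel)
  expect_equal(unname(d1$mean_rank), unname(d0$mean_rank[gam]))
  expect_equal(unname(d1$pair), unname(d0$pair[gam, gam]))
  expect_equal(unname(d1$marginal), unname(d0$marginal[gam, ]))
})

test_that("imputed ties drop pair/marginal with a warning but keep mean rank", {
  tied <- data.frame(a = c(1, 1), b = c(2.5, 2), c = c(2.5, 3))
  expect_warning(d <- destat(tied), "tied")
  expect_null(d$pair)
  expect_null(d$marginal)
  expect_equal(unname(d$mean_rank), c(1, 2.25, 2.75))
})

test_that("the pair-matrix direction option flips the convention", {
  d1 <- destat(tiny_table(), direction = "rank_exceeds")
  d2 <- destat(tiny_table(), direction = "beats")
  expect_equal(unname(d1$pair), unname(t(d2$pair)))
})

test_that("rank_expand inverts rank_agg", {
  ind <- random_rankings(3, 40, seed = 7)
  back <- rank_expand(rank_agg(ind))
  expect_equal(rank_agg(back), rank_agg(ind))
})
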