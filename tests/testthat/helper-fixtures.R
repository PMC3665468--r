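# Fixtures built in code: tiny canonical tables, random tables under a
# seed, and a two-cluster label-ranking problem.

# aggregated table {(1,2,3): 2}
tiny_table <- function() {
  tibble::tibble(a = 1, b = 2, c = 3, n = 2)
}

# all k! permutations with equal frequency
balanced_table <- function(k, freq = 1) {
  tab <- tibble::as_tibble(as.data.frame(permutations_of(k)))
  names(tab) <- paste0("item", seq_len(k))
  tab$n <- freq
  tab
}

# N uniform random rankings of k items (individual format)
random_rankings <- function(k, n, seed = NULL) {
  perms <- permutations_of(k)
  idx <- if (is.null(seed)) sample.int(nrow(perms), n, replace = TRUE) else
    withr::with_seed(seed, sample.int(nrow(perms), n, replace = TRUE))
  out <- tibble::as_tibble(as.data.frame(perms[idx, , drop = FALSE]))
  names(out) <- paste0("item", seq_len(k))
  out
}

# perfectly separable label-ranking problem: two covariate clusters far
# apart, each with its own fixed ranking of 4 items
two_cluster_fixture <- function(n_per = 30) {
  r1 <- c(1, 2, 3, 4)
  r2 <- c(4, 3, 2, 1)
  rankings <- rbind(
    matrix(r1, n_per, 4, byrow = TRUE),
    matrix(r2, n_per, 4, byrow = TRUE)
  )
  colnames(rankings) <- paste0("item", 1:4)
  cov <- withr::with_seed(99, tibble::tibble(
    x1 = c(rnorm(n_per, -5, 0.5), rnorm(n_per, 5, 0.5)),
    x2 = c(rnorm(n_per, -5, 0.5), rnorm(n_per, 5, 0.5))
  ))
  list(rankings = tibble::as_tibble(as.data.frame(rankings)),
       covariates = cov,
       cluster = rep(1:2, each = n_per),
       cluster_rankings = list(r1, r2))
}

# consistent comparison matrix from a positive weight vector
consistent_cm <- function(w) outer(w, w, "/")

expect_tab_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
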