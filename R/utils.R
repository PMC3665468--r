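# Internal helpers shared across the package.

# cache of permutation matrices, keyed by k
.perm_cache <- new.env(parent = emptyenv())

#' All permutations of 1..k
#'
#' Enumerates the symmetric group S_k as a `k! x k` integer matrix in
#' lexicographic row order. Rows can be read either as rankings or as
#' orderings; the set is the same. Enumeration is capped (default k <= 8,
#' i.e. 40320 rows) because every downstream use is an exact sum over S_k.
#'
#' @param k number of items.
#' @param max_k enumeration cap; override via `options(rankery.max_k = )`.
#' @return integer matrix with `factorial(k)` rows and `k` columns.
#' @export
permutations_of <- function(k, max_k = getOption("rankery.max_k", 8L)) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (k > max_k) {
    stop("enumeration of S_", k, " exceeds the cap (", max_k,
         "); raise options(rankery.max_k = ) if you really want ",
         factorial(k), " permutations")
  }
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (k == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- permutations_of(k - 1L, max_k = max_k)
    blocks <- lapply(seq_len(k), function(i) {
      rest <- setdiff(seq_len(k), i)
      cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
    })
    do.call(rbind, blocks)
  }
  dimnames(res) <- NULL
  storage.mode(res) <- "integer"
  .perm_cache[[key]] <- res
  res
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is untouched. seed = NULL means "use current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# TRUE when x is (numerically) a permutation of 1..k
is_permutation <- function(x) {
  k <- length(x)
  !anyNA(x) && isTRUE(all.equal(sort(as.numeric(x)), as.numeric(seq_len(k)),
                                tolerance = 1e-9))
}

# TRUE when x is a complete ranking possibly carrying mean-rank imputed ties:
# positive entries summing to k(k+1)/2
is_ranking <- function(x) {
  k <- length(x)
  !anyNA(x) && all(x > 0) &&
    isTRUE(all.equal(sum(as.numeric(x)), k * (k + 1) / 2, tolerance = 1e-8))
}

# row-wise reverse cumulative sum via one matrix product (used in the
# Plackett-Luce likelihood: denom[, j] = sum over l >= j of x[, l])
rev_cumsum_rows <- function(x) {
  k <- ncol(x)
  m <- matrix(0, k, k)
  m[lower.tri(m, diag = TRUE)] <- 1
  x %*% m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
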