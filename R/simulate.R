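# Synthetic ranking-data generators: exact samplers for every model family
# in the package. Because the package caps enumeration at k <= 8, the
# distance-family samplers draw directly from the exact probability table
# over S_k (no MCMC). Every sampler takes a seed and leaves the caller's
# RNG state untouched.

#' Sample rankings from the Luce model
#'
#' Draws rankings by the vase process: at each stage the next-ranked item
#' is selected with probability proportional to the utilities of the items
#' not yet ranked.
#'
#' @param v positive utility vector (length k).
#' @param n number of judges to sample.
#' @param seed RNG seed; the global RNG state is preserved.
#' @return tibble of `n` individual rankings (columns `item1..itemk`).
#' @examples
#' sample_luce(c(4, 2, 1), 5, seed = 1)
#' @export
sample_luce <- function(v, n, seed = NULL) {
  if (any(v <= 0) || anyNA(v)) stop("utilities must be positive")
  k <- length(v)
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, k)
    colnames(out) <- paste0("item", seq_len(k))
    return(tibble::as_tibble(as.data.frame(out)))
  }
  with_seed(seed, {
    ranks <- matrix(0L, n, k)
    alive <- matrix(TRUE, n, k)
    V <- matrix(v, n, k, byrow = TRUE)
    ut <- matrix(0, k, k)
    ut[upper.tri(ut, diag = TRUE)] <- 1
    for (j in seq_len(k - 1L)) {
      W <- V * alive
      cum <- W %*% ut # cum[, i] = sum over l <= i
      # inverse-CDF draw among remaining items
      u <- stats::runif(n) * cum[, k]
      pick <- max.col(cum >= u, ties.method = "first")
      ranks[cbind(seq_len(n), pick)] <- j
      alive[cbind(seq_len(n), pick)] <- FALSE
    }
    last <- max.col(alive, ties.method = "first")
    ranks[cbind(seq_len(n), last)] <- k
    colnames(ranks) <- paste0("item", seq_len(k))
    tibble::as_tibble(as.data.frame(ranks))
  })
}

#' Sample rankings from a distance-family model
#'
#' Exact sampling from the distance-based, phi-component or weighted
#' distance-based model: the full probability table over S_k is enumerated
#' and rankings are drawn from it. Supply exactly one of `lambda` (single
#' dispersion), `lambdas` (stagewise, phi-component) or `weights`
#' (weighted model, dispersion absorbed into the weights).
#'
#' @param n number of rankings to draw.
#' @param pi0 modal ranking.
#' @param lambda dispersion of the single-dispersion model.
#' @param lambdas length `k - 1` stage dispersions.
#' @param weights length `k` nonnegative rank-position weights.
#' @param dtype distance type for `lambda` / `weights` models.
#' @param seed RNG seed.
#' @return tibble of `n` individual rankings.
#' @examples
#' sample_dbm(5, pi0 = c(1, 2, 3), lambda = log(2), seed = 1)
#' @export
sample_dbm <- function(n, pi0, lambda = NULL, lambdas = NULL, weights = NULL,
                       dtype = c("tau", "rho", "rho2", "foot"), seed = NULL) {
  dtype <- match.arg(dtype)
  if (!is_permutation(pi0)) stop("pi0 must be a complete ranking")
  if (sum(!is.null(lambda), !is.null(lambdas), !is.null(weights)) != 1L) {
    stop("supply exactly one of lambda, lambdas or weights")
  }
  k <- length(pi0)
  probs <- if (!is.null(lambdas)) {
    probs_phicom(pi0, lambdas)
  } else if (!is.null(weights)) {
    probs_wdbm(pi0, weights, dtype)
  } else {
    probs_dbm(pi0, lambda, dtype)
  }
  perms <- permutations_of(k)
  with_seed(seed, {
    idx <- sample.int(nrow(perms), n, replace = TRUE, prob = probs)
    out <- perms[idx, , drop = FALSE]
    colnames(out) <- paste0("item", seq_len(k))
    tibble::as_tibble(as.data.frame(out))
  })
}

#' Generate a covariate-driven ranking fixture (rank-ordered logit data)
#'
#' Draws judge covariates (standard normal, or two shifted clusters) and
#' samples each judge's ranking from the Luce model with utilities
#' `exp(beta %*% c(1, x))`. This is the generator behind the rank-ordered
#' logit recovery checks and the label-ranking examples.
#'
#' @param n number of judges.
#' @param k number of items.
#' @param m number of covariates.
#' @param beta `k x (m + 1)` coefficient matrix (intercept first); the
#'   utilities are `exp` of the linear predictor, so a zero matrix gives
#'   uniform rankings.
#' @param seed RNG seed.
#' @param clusters if `> 1`, covariates are drawn in this many clusters
#'   with means spaced `cluster_sep` apart on every covariate; the tibble
#'   gains a `cluster` column in the output's `covariates`.
#' @param cluster_sep separation between consecutive cluster means.
#' @return list with `rankings` (`n x k` tibble) and `covariates`
#'   (`n x m` tibble, plus `cluster` when clustered).
#' @export
make_rol_fixture <- function(n, k, m, beta, seed = NULL, clusters = 1L,
                             cluster_sep = 5) {
  beta <- as.matrix(beta)
  if (nrow(beta) != k || ncol(beta) != m + 1L) {
    stop("beta must be a k x (m + 1) matrix")
  }
  with_seed(seed, {
    cl <- rep_len(seq_len(clusters), n)
    X <- matrix(stats::rnorm(n * m), n, m)
    if (clusters > 1L && m > 0L) {
      X <- X + (cl - (clusters + 1) / 2) * cluster_sep
    }
    eta <- cbind(1, X) %*% t(beta) # n x k log-utilities
    ranks <- matrix(0L, n, k)
    for (i in seq_len(n)) {
      # vase draw with judge-specific utilities, inlined for judge i
      ranks[i, ] <- draw_one_luce(exp(eta[i, ]))
    }
    colnames(ranks) <- paste0("item", seq_len(k))
    cov <- matrix(X, n, m)
    colnames(cov) <- if (m > 0L) paste0("x", seq_len(m)) else character(0)
    cov <- tibble::as_tibble(as.data.frame(cov))
    if (clusters > 1L) cov$cluster <- cl
    list(rankings = tibble::as_tibble(as.data.frame(ranks)),
         covariates = cov)
  })
}

# one vase draw given utilities; returns the ranking vector
draw_one_luce <- function(v) {
  k <- length(v)
  ranks <- integer(k)
  alive <- rep(TRUE, k)
  for (j in seq_len(k)) {
    pool <- which(alive)
    pick <- if (length(pool) == 1L) pool else {
      pool[sample.int(length(pool), 1L, prob = v[pool])]
    }
    ranks[pick] <- j
    alive[pick] <- FALSE
  }
  ranks
}
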