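# Right-invariant distances between complete rankings, their weighted
# generalizations, and the stagewise (adjacent-transposition) decomposition
# of Kendall's tau.
#
# Weighted distances attach a nonnegative weight to each rank position of
# the reference ranking sigma (the modal ranking pi0 in model fitting): the
# weight entering for item i is w[sigma(i)]. Kendall's tau uses the product
# w[sigma(i)] * w[sigma(j)] per discordant pair; the Spearman and footrule
# families weight the per-item displacement terms.

.dtypes <- c("tau", "rho", "rho2", "foot")

#' Distance between two complete rankings
#'
#' Supported distances (`dtype`):
#' * `"tau"` — Kendall's tau: number of discordant item pairs;
#' * `"rho"` — Spearman's rho: square root of the sum of squared rank
#'   differences;
#' * `"rho2"` — Spearman's rho square: sum of squared rank differences;
#' * `"foot"` — Spearman's footrule: sum of absolute rank differences.
#'
#' All four are right invariant: relabeling the items in both rankings
#' leaves the distance unchanged. With `weights` supplied, `sigma` plays the
#' role of the reference ranking whose rank positions index the weights
#' (see above); `weights = NULL` is the unweighted case (all ones).
#'
#' @param pi,sigma complete (untied) rankings of the same k items.
#' @param dtype distance type.
#' @param weights optional length-k nonnegative rank-position weights.
#' @return the distance as a double (even when integral).
#' @examples
#' rank_distance(c(1, 2, 3), c(3, 2, 1), "tau") # 3: all pairs flipped
#' @export
rank_distance <- function(pi, sigma, dtype = c("tau", "rho", "rho2", "foot"),
                          weights = NULL) {
  dtype <- match.arg(dtype)
  if (length(pi) != length(sigma)) stop("rankings differ in length")
  if (!is_permutation(pi) || !is_permutation(sigma)) {
    stop("both arguments must be complete (untied) rankings of 1..k")
  }
  check_weights(weights, length(pi))
  drop(dist_many(matrix(pi, 1L), sigma, dtype, weights))
}

check_weights <- function(weights, k) {
  if (is.null(weights)) return(invisible())
  if (length(weights) != k) stop("weights must have length k = ", k)
  if (anyNA(weights) || any(weights < 0)) stop("weights must be nonnegative")
  invisible()
}

# Vectorized distances from every row of R (rankings) to pi0.
dist_many <- function(R, pi0, dtype, weights = NULL) {
  k <- length(pi0)
  wt <- if (is.null(weights)) rep(1, k) else weights[pi0]
  if (dtype == "tau") {
    tot <- numeric(nrow(R))
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        disc <- (R[, i] - R[, j]) * (pi0[i] - pi0[j]) < 0
        tot <- tot + wt[i] * wt[j] * disc
      }
    }
    tot
  } else {
    D <- sweep(R, 2L, pi0)
    if (dtype == "foot") return(drop(abs(D) %*% wt))
    s <- drop((D * D) %*% wt)
    if (dtype == "rho2") s else sqrt(s)
  }
}

# Linear "design" for weighted distances: returns a matrix A and a rule so
# that the distance of each row of R to pi0 is A %*% g(w), where g(w) is
# w[r] per rank position r (foot/rho2/rho) or w[r] * w[s] per rank-position
# pair r < s (tau). Lets model fitting re-evaluate distances for many weight
# vectors with one matrix-vector product.
dist_design <- function(R, pi0, dtype) {
  k <- length(pi0)
  inv <- order(pi0) # inv[r] = item holding rank r under pi0
  if (dtype == "tau") {
    pr <- which(upper.tri(diag(k)), arr.ind = TRUE) # rank-position pairs r < s
    A <- matrix(0, nrow(R), nrow(pr))
    for (p in seq_len(nrow(pr))) {
      i <- inv[pr[p, 1L]]
      j <- inv[pr[p, 2L]]
      A[, p] <- (R[, i] - R[, j]) * (pi0[i] - pi0[j]) < 0
    }
    list(A = A, pairs = pr, dtype = dtype)
  } else {
    A <- abs(R[, inv, drop = FALSE] - rep(seq_len(k), each = nrow(R)))
    if (dtype != "foot") A <- A * A
    list(A = A, pairs = NULL, dtype = dtype)
  }
}

# Evaluate the weighted distance from a design (see dist_design).
dist_eval <- function(design, w) {
  g <- if (design$dtype == "tau") {
    w[design$pairs[, 1L]] * w[design$pairs[, 2L]]
  } else {
    w
  }
  d <- drop(design$A %*% g)
  if (design$dtype == "rho") sqrt(d) else d
}

#' Stagewise decomposition of Kendall's tau
#'
#' Decomposes the Kendall distance from `pi` to the reference `pi0` into
#' `k - 1` stage counts `v`. Stage `i` concerns the item ranked `i`-th by
#' `pi0`; `v[i]` counts the items ranked below it by `pi0` that `pi`
#' nevertheless prefers — the "mistakes" made at stage `i`, i.e. the
#' adjacent transpositions needed to move that item into position. The
#' counts satisfy `v[i] <= k - i` and `sum(v)` equals Kendall's tau.
#'
#' @param pi complete ranking.
#' @param pi0 reference (modal) ranking.
#' @return integer vector of length `k - 1`.
#' @examples
#' stage_counts(c(2, 1, 3), c(1, 2, 3)) # c(1, 0)
#' @export
stage_counts <- function(pi, pi0) {
  if (!is_permutation(pi) || !is_permutation(pi0)) {
    stop("stage counts are undefined for tied rankings")
  }
  drop(stage_counts_many(matrix(pi, 1L), pi0))
}

# Vectorized stage counts: rows of R vs pi0; returns nrow(R) x (k-1).
stage_counts_many <- function(R, pi0) {
  k <- length(pi0)
  inv <- order(pi0)
  V <- matrix(0L, nrow(R), k - 1L)
  for (i in seq_len(k - 1L)) {
    below <- inv[seq.int(i + 1L, k)] # items pi0 ranks below stage-i item
    V[, i] <- rowSums(R[, below, drop = FALSE] < R[, inv[i]])
  }
  V
}
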