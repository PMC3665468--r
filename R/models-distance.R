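# Distance-based (Mallows-type), phi-component and weighted distance-based
# models. All three put probability exp(-"distance to a modal ranking pi0")
# over S_k, differing in how dispersion enters:
#   dbm:    P(pi) = exp(-lambda * d(pi, pi0)) / C(lambda)     (one lambda)
#   phicom: P(pi) = exp(-sum_i lambda_i * v_i(pi, pi0)) / C(Lambda)
#           with v the Kendall stage counts (one lambda per stage)
#   wdbm:   P(pi) = exp(-d_w(pi, pi0)) / C(w)                 (rank weights
#           absorb the dispersion scale; no separate lambda)
# Normalizing constants are exact: closed form for Kendall/phi-component,
# brute-force summation over S_k otherwise (hence the enumeration cap).

#' Log normalizing constant of a distance-based model
#'
#' Computes `log C`, where `C = sum over S_k of exp(-lambda * d(pi, pi0))`
#' (or `exp(-d_w(pi, pi0))` when `weights` are supplied, or
#' `exp(-sum_i lambda_i v_i)` when stagewise `lambdas` are supplied).
#' For the unweighted Kendall distance and for the phi-component model the
#' product closed form is used unless `method = "enumerate"` forces the
#' brute-force sum; the two agree to numerical precision. Right invariance
#' makes the constant independent of `pi0`.
#'
#' @param k number of items.
#' @param lambda dispersion parameter (single-dispersion model).
#' @param dtype distance type, see [rank_distance()].
#' @param weights rank-position weights of the weighted model.
#' @param lambdas stagewise dispersions of the phi-component model.
#' @param method `"auto"` uses closed forms where they exist.
#' @return `log C` as a single number.
#' @examples
#' exp(log_C(3, lambda = log(2))) # 2.625
#' @export
log_C <- function(k, lambda = NULL, dtype = "tau", weights = NULL,
                  lambdas = NULL, method = c("auto", "enumerate")) {
  method <- match.arg(method)
  dtype <- match.arg(dtype, .dtypes)
  if (!is.null(lambdas)) {
    if (length(lambdas) != k - 1L) stop("lambdas must have length k - 1")
    if (method == "auto") return(log_C_phi(k, lambdas))
    perms <- permutations_of(k)
    V <- stage_counts_many(perms, seq_len(k))
    return(logsumexp(-drop(V %*% lambdas)))
  }
  if (!is.null(weights)) {
    check_weights(weights, k)
    perms <- permutations_of(k)
    return(logsumexp(-dist_many(perms, seq_len(k), dtype, weights)))
  }
  if (is.null(lambda) || lambda < 0) stop("lambda must be nonnegative")
  if (dtype == "tau" && method == "auto") return(log_C_tau(k, lambda))
  perms <- permutations_of(k)
  logsumexp(-lambda * dist_many(perms, seq_len(k), dtype))
}

# closed form for Kendall's tau: C = prod_{i=1}^{k-1}
#   (1 - exp(-(k - i + 1) lambda)) / (1 - exp(-lambda))
log_C_tau <- function(k, lambda) {
  log_C_phi(k, rep(lambda, k - 1L))
}

# phi-component closed form; the lambda -> 0 limit of factor i is k - i + 1
log_C_phi <- function(k, lambdas) {
  i <- seq_len(k - 1L)
  m <- k - i + 1L
  term <- ifelse(lambdas < 1e-12,
                 log(m),
                 log(-expm1(-m * lambdas)) - log(-expm1(-lambdas)))
  sum(term)
}

# Greedy local search over modal rankings: repeatedly take the best
# pairwise swap of two items' ranks; used when k is too large to try all
# k! candidates. `objective(pi0)` is minimized.
pi0_local_search <- function(start, objective) {
  k <- length(start)
  cur <- start
  cur_val <- objective(cur)
  repeat {
    best <- NULL
    best_val <- cur_val
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        cand <- cur
        cand[c(i, j)] <- cand[c(j, i)]
        val <- objective(cand)
        if (val < best_val - 1e-12) {
          best <- cand
          best_val <- val
        }
      }
    }
    if (is.null(best)) return(cur)
    cur <- best
    cur_val <- best_val
  }
}

# candidate modal rankings: exhaustive up to `exhaustive_k`, otherwise a
# pairwise-swap local search seeded at the mean-rank ordering
pi0_candidates <- function(p, objective, exhaustive_k = 6L) {
  if (p$k <= exhaustive_k) {
    perms <- permutations_of(p$k)
    vals <- apply(perms, 1L, objective)
    list(best = perms[which.min(vals), ],
         ties = perms[vals < min(vals) + 1e-9, , drop = FALSE])
  } else {
    mr <- colSums(p$R * p$freq) / p$N
    start <- rank(mr, ties.method = "first")
    best <- pi0_local_search(start, objective)
    list(best = best, ties = matrix(best, 1L))
  }
}

#' Fit a distance-based (Mallows-type) ranking model
#'
#' Maximum likelihood over the modal ranking `pi0` and the dispersion
#' `lambda` of `P(pi) = exp(-lambda d(pi, pi0)) / C(lambda)`. Because
#' `C(lambda)` does not depend on `pi0` (right invariance), the optimal
#' modal ranking minimizes the frequency-weighted mean distance, and the
#' dispersion then solves a one-dimensional concave problem. The modal
#' ranking is found exhaustively for `k <= 6` and by pairwise-swap local
#' search seeded at the mean-rank ordering for larger `k`.
#'
#' @param x individual or aggregated ranking table.
#' @param dtype distance type, see [rank_distance()].
#' @param lambda_max upper bound of the dispersion search; the estimate
#'   hitting this bound (degenerate, e.g. a single observed ranking)
#'   triggers a warning.
#' @return a `rank_fit` with fields `pi0`, `lambda`, `dtype`, `loglik`,
#'   `gof`; co-optimal modal rankings, if any, are in `pi0_ties`.
#' @examples
#' fit_dbm(sample_dbm(300, pi0 = c(1, 2, 3, 4), lambda = 1, seed = 1))
#' @export
fit_dbm <- function(x, dtype = c("tau", "rho", "rho2", "foot"),
                    lambda_max = 30) {
  dtype <- match.arg(dtype)
  p <- rt_parts(x, allow_ties = FALSE,
                what = "model fitting requires strict permutations; rankings")
  k <- p$k
  perms <- permutations_of(k) # also enforces the enumeration cap
  d_all0 <- if (dtype == "tau") NULL else dist_many(perms, seq_len(k), dtype)
  logC <- function(lam) {
    if (dtype == "tau") log_C_tau(k, lam) else logsumexp(-lam * d_all0)
  }
  dbar <- function(pi0) sum(p$freq * dist_many(p$R, pi0, dtype)) / p$N
  cand <- pi0_candidates(p, dbar)
  pi0 <- cand$best
  db <- dbar(pi0)
  ll <- function(lam) -lam * p$N * db - p$N * logC(lam)
  opt <- stats::optimize(ll, c(0, lambda_max), maximum = TRUE, tol = 1e-9)
  lambda <- opt$maximum
  if (ll(0) >= opt$objective) { # balanced data: uniform limit
    lambda <- 0
    opt$objective <- ll(0)
  }
  if (lambda > 0.99 * lambda_max) {
    warning("dispersion estimate is at the search bound (lambda_max = ",
            lambda_max, "); the data are degenerately concentrated")
  }
  gof <- gof_or_null(p, probs_dbm(pi0, lambda, dtype), 1L)
  if (nrow(cand$ties) > 1L) {
    warning(nrow(cand$ties), " modal rankings are co-optimal; reporting the ",
            "lexicographically first (see pi0_ties)")
  }
  new_rank_fit("dbm", p, opt$objective, 1L,
               extra = list(pi0 = pi0, lambda = lambda, dtype = dtype,
                            mean_distance = db, pi0_ties = cand$ties),
               gof = gof)
}

#' Fit the phi-component model
#'
#' The phi-component model extends the Mallows model with Kendall's tau by
#' giving each stage of the tau decomposition its own dispersion:
#' `P(pi) = exp(-sum_i lambda_i v_i(pi, pi0)) / C(Lambda)` with the stage
#' counts `v` of [stage_counts()] and the product closed form for
#' `C(Lambda)`. Given `pi0` the loglikelihood separates across stages, so
#' each `lambda_i` solves its own one-dimensional problem. Constraining
#' `lambda_1 = ... = lambda_{k-1}` recovers the Mallows model.
#'
#' @inheritParams fit_dbm
#' @return a `rank_fit` with fields `pi0`, `lambdas`, `loglik`, `gof`.
#' @export
fit_phicom <- function(x, lambda_max = 30) {
  p <- rt_parts(x, allow_ties = FALSE,
                what = "model fitting requires strict permutations; rankings")
  k <- p$k
  permutations_of(k) # enforce enumeration cap (GOF needs it)
  fit_given_pi0 <- function(pi0) {
    V <- stage_counts_many(p$R, pi0)
    S <- colSums(p$freq * V)
    lambdas <- numeric(k - 1L)
    ll <- 0
    for (i in seq_len(k - 1L)) {
      m <- k - i + 1L
      f <- function(lam) {
        -lam * S[i] - p$N * (log(-expm1(-m * max(lam, 1e-300))) -
                               log(-expm1(-max(lam, 1e-300))))
      }
      f0 <- -p$N * log(m)
      opt <- stats::optimize(f, c(1e-8, lambda_max), maximum = TRUE,
                             tol = 1e-9)
      if (f0 >= opt$objective) {
        lambdas[i] <- 0
        ll <- ll + f0
      } else {
        lambdas[i] <- opt$maximum
        ll <- ll + opt$objective
      }
    }
    list(lambdas = lambdas, loglik = ll)
  }
  cand <- pi0_candidates(p, function(pi0) -fit_given_pi0(pi0)$loglik)
  pi0 <- cand$best
  best <- fit_given_pi0(pi0)
  if (any(best$lambdas > 0.99 * lambda_max)) {
    warning("some stage dispersions are at the search bound; the data are ",
            "degenerately concentrated in those stages")
  }
  gof <- gof_or_null(p, probs_phicom(pi0, best$lambdas), k - 1L)
  new_rank_fit("phicom", p, best$loglik, k - 1L,
               extra = list(pi0 = pi0, lambdas = best$lambdas,
                            pi0_ties = cand$ties),
               gof = gof)
}

#' Fit a weighted distance-based model
#'
#' Maximum likelihood for `P(pi) = exp(-d_w(pi, pi0)) / C(w)` with
#' nonnegative rank-position weights `w` (see [rank_distance()]). The
#' weights absorb the dispersion scale, so there is no separate lambda: a
#' fit constrained to equal weights coincides with the unweighted model at
#' the matching dispersion. A large `w_r` means judges strongly agree on
#' which item belongs at rank `r` of the modal ranking. For each candidate
#' modal ranking the weights are optimized by box-constrained quasi-Newton;
#' candidates are exhaustive for `k <= 5` and a pairwise-swap local search
#' otherwise (the per-candidate optimization makes the exhaustive sweep
#' costly sooner than in [fit_dbm()]).
#'
#' @inheritParams fit_dbm
#' @param w_max upper box bound for the weights.
#' @return a `rank_fit` with fields `pi0`, `weights`, `dtype`, `loglik`,
#'   `gof`.
#' @export
fit_wdbm <- function(x, dtype = c("tau", "rho", "rho2", "foot"), w_max = 50) {
  dtype <- match.arg(dtype)
  p <- rt_parts(x, allow_ties = FALSE,
                what = "model fitting requires strict permutations; rankings")
  k <- p$k
  perms <- permutations_of(k)
  d_all0 <- dist_many(perms, seq_len(k), dtype)
  fit_given_pi0 <- function(pi0) {
    des_data <- dist_design(p$R, pi0, dtype)
    des_all <- dist_design(perms, pi0, dtype)
    nll <- function(w) {
      sum(p$freq * dist_eval(des_data, w)) +
        p$N * logsumexp(-dist_eval(des_all, w))
    }
    # Start at the equal-weight solution matching the unweighted fit's
    # dispersion: the surface has a spurious stationary corner at w = 0
    # (the uniform model) that can trap an arbitrary start, whereas the
    # matched equal-weight point is already on the likelihood ridge.
    db <- sum(p$freq * dist_many(p$R, pi0, dtype)) / p$N
    lam_opt <- stats::optimize(function(l) -l * db - logsumexp(-l * d_all0),
                               c(0, 30), maximum = TRUE, tol = 1e-8)$maximum
    w0 <- switch(dtype, tau = sqrt(lam_opt), rho = lam_opt^2, lam_opt)
    starts <- list(rep(max(w0, 1e-3), k), rep(1, k))
    best <- NULL
    for (st in starts) {
      opt <- stats::optim(st, nll, method = "L-BFGS-B",
                          lower = 0, upper = w_max,
                          control = list(maxit = 500, factr = 1e4))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    list(weights = best$par, loglik = -best$value)
  }
  cand <- pi0_candidates(p, function(pi0) -fit_given_pi0(pi0)$loglik,
                         exhaustive_k = 5L)
  pi0 <- cand$best
  best <- fit_given_pi0(pi0)
  w <- best$weights
  names(w) <- paste0("rank", seq_len(k))
  gof <- gof_or_null(p, probs_wdbm(pi0, w, dtype), k)
  new_rank_fit("wdbm", p, best$loglik, k,
               extra = list(pi0 = pi0, weights = w, dtype = dtype,
                            pi0_ties = cand$ties),
               gof = gof)
}
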