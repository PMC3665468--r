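# Luce (Plackett-Luce) model and its covariate extension, the rank-ordered
# logit. A ranking is built stagewise: at each stage the next-ranked item
# is drawn with probability proportional to the utilities of the items
# still unranked (the "vase" interpretation). The loglikelihood in the
# log-utilities is globally concave, so quasi-Newton ascent from any start
# reaches the global maximum.

# Stagewise loglikelihood, one row per judge.
# logV: n x k matrix of log-utilities; ordmat: n x k orderings (items by
# rank). Row-wise max is subtracted before exponentiating for stability.
pl_loglik_rows <- function(logV, ordmat) {
  n <- nrow(logV)
  k <- ncol(logV)
  idx <- cbind(rep(seq_len(n), k), as.vector(ordmat))
  lv_ord <- matrix(logV[idx], n, k)
  lv_ord <- lv_ord - apply(lv_ord, 1L, max)
  den <- rev_cumsum_rows(exp(lv_ord))
  rowSums(lv_ord[, seq_len(k - 1L), drop = FALSE] -
            log(den[, seq_len(k - 1L), drop = FALSE]))
}

#' Probability of an ordering under the Luce model
#'
#' The Luce model assigns utility `V_i > 0` to item `i`; the probability of
#' observing ordering `o` (items listed by rank) is the product over stages
#' `j = 1..k-1` of `V[o_j] / sum(V[o_j..o_k])`: at every stage the
#' next-preferred item is drawn proportionally to the utilities remaining.
#'
#' @param v positive utility vector.
#' @param ordering item ordering (most preferred first).
#' @return the probability.
#' @examples
#' luce_prob(c(2, 1, 1), c(1, 2, 3)) # (2/4) * (1/2) = 0.25
#' @export
luce_prob <- function(v, ordering) {
  if (any(v <= 0) || anyNA(v)) stop("utilities must be positive")
  if (!is_permutation(ordering)) stop("ordering must be a permutation of items")
  if (length(v) != length(ordering)) stop("length mismatch")
  exp(pl_loglik_rows(matrix(log(v), 1L), matrix(ordering, 1L)))
}

#' Fit the Luce (Plackett-Luce) model by maximum likelihood
#'
#' Maximizes the stagewise loglikelihood over log-utilities with the
#' reference item's utility fixed at 1 for identifiability. The
#' loglikelihood is globally concave, so the optimum does not depend on the
#' starting point.
#'
#' @param x individual or aggregated ranking table (strict permutations).
#' @param ref reference item whose utility is fixed at 1 (default: item k).
#' @param start optional numeric start for the free log-utilities.
#' @return a `rank_fit` with fields `utilities`, `loglik`, `gof` (Pearson
#'   chi-squared over all `k!` rankings when `k` is within the enumeration
#'   cap) and a `boundary` flag set when estimates run away (e.g. an item
#'   that every judge ranks last).
#' @examples
#' fit_luce(sample_luce(c(4, 2, 1, 1), 500, seed = 1))
#' @export
fit_luce <- function(x, ref = NULL, start = NULL) {
  p <- rt_parts(x, allow_ties = FALSE,
                what = "model fitting requires strict permutations; rankings")
  k <- p$k
  ref <- ref %||% k
  stopifnot(ref >= 1, ref <= k)
  ordm <- t(apply(p$R, 1L, order))
  free <- setdiff(seq_len(k), ref)
  nll <- function(theta) {
    logv <- numeric(k)
    logv[free] <- theta
    logV <- matrix(logv, nrow(ordm), k, byrow = TRUE)
    -sum(p$freq * pl_loglik_rows(logV, ordm))
  }
  theta0 <- start %||% rep(0, k - 1L)
  opt <- stats::optim(theta0, nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  boundary <- any(abs(opt$par) > 10)
  if (boundary) {
    warning("log-utility estimates are diverging (some item is at the ",
            "boundary, e.g. always ranked last); estimates unreliable")
  }
  logv <- numeric(k)
  logv[free] <- opt$par
  utilities <- exp(logv)
  names(utilities) <- p$items
  loglik <- -opt$value
  gof <- if (k <= getOption("rankery.max_k", 8L)) {
    gof_or_null(p, probs_luce(utilities, k), k - 1L)
  }
  new_rank_fit("luce", p, loglik, k - 1L,
               extra = list(utilities = utilities, ref = ref,
                            boundary = boundary),
               gof = gof)
}

#' Fit the rank-ordered logit model
#'
#' Extends the Luce model with judge covariates: judge `n`'s utility for
#' item `j` is `V_nj = exp(beta_j0 + sum_m beta_jm x_nm)`, with the
#' reference item's coefficients fixed at zero. The exponential link keeps
#' utilities positive for any coefficient values. Standard errors come from
#' the observed information (numerical Hessian at the optimum) and p-values
#' are Wald z-tests.
#'
#' @param rankings individual `N x k` ranking table (strict permutations).
#' @param covariates `N x M` data frame of numeric judge covariates
#'   (`M = 0`, i.e. zero columns, reduces the model to the plain Luce model).
#' @param ref reference item (default: item k).
#' @return a `rank_fit` with a `coef` tibble (item, term, estimate,
#'   std.error, statistic, p.value) and the fitted `beta` matrix.
#' @export
fit_rol <- function(rankings, covariates, ref = NULL) {
  p <- rt_parts(rankings, allow_ties = FALSE,
                what = "model fitting requires strict permutations; rankings")
  if (any(p$freq != 1)) {
    stop("fit_rol needs individual rankings (one row per judge), ",
         "not an aggregated table")
  }
  k <- p$k
  ref <- ref %||% k
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(p$R)) {
    stop("covariates must have one row per judge")
  }
  if (anyNA(covariates)) stop("covariates must be complete (no NA)")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (!is.numeric(X)) stop("covariates must be numeric")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("collinear covariates: ", paste(bad, collapse = ", "))
  }
  M1 <- ncol(X) # M + 1 terms per non-reference item
  free <- setdiff(seq_len(k), ref)
  ordm <- t(apply(p$R, 1L, order))
  nll <- function(theta) {
    B <- matrix(0, k, M1)
    B[free, ] <- matrix(theta, k - 1L, M1)
    -sum(pl_loglik_rows(X %*% t(B), ordm))
  }
  opt <- stats::optim(rep(0, (k - 1L) * M1), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12),
                      hessian = TRUE)
  est <- opt$par
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, length(est)) else sqrt(pmax(diag(vc), 0))
  z <- est / se
  beta <- matrix(0, k, M1, dimnames = list(p$items, colnames(X)))
  beta[free, ] <- matrix(est, k - 1L, M1)
  coef_tbl <- tibble::tibble(
    item = rep(p$items[free], M1),
    term = rep(colnames(X), each = k - 1L),
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = 2 * stats::pnorm(-abs(z))
  )
  new_rank_fit("rol", p, -opt$value, (k - 1L) * M1,
               extra = list(beta = beta, coef = coef_tbl, ref = ref,
                            vcov = vc))
}

#' Predicted utilities and rankings from a rank-ordered logit fit
#'
#' @param object a `rank_fit` of family `"rol"`.
#' @param newdata data frame of covariates for new judges.
#' @param ... unused.
#' @return tibble of predicted rankings (items ordered by decreasing
#'   fitted utility; ties broken by item index).
#' @export
predict.rank_fit <- function(object, newdata, ...) {
  if (object$family != "rol") {
    stop("predict is only available for rank-ordered logit fits")
  }
  X <- cbind(1, as.matrix(as.data.frame(newdata)))
  if (ncol(X) != ncol(object$beta)) {
    stop("newdata must supply the ", ncol(object$beta) - 1L,
         " covariate(s) used in the fit")
  }
  U <- X %*% t(object$beta) # log-utilities per judge
  out <- t(apply(U, 1L, function(u) rank(-u, ties.method = "first")))
  colnames(out) <- object$items
  tibble::as_tibble(as.data.frame(out))
}
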