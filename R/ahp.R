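# Analytic Hierarchy Process: criterion weights from a positive reciprocal
# pairwise comparison matrix, with Saaty's and Koczkodaj's inconsistency
# indices. A matrix is perfectly consistent when a_st * a_tu = a_su for all
# triads, in which case the principal eigenvalue equals k and both indices
# are zero.

# Random-index table for Saaty's consistency ratio, RI_k = E[(lambda_max -
# k) / (k - 1)] over random reciprocal matrices with upper-triangle entries
# uniform on the 17-point scale {1/9..1/2, 1..9}. Values below were
# produced by simulate_ri(k, reps = 100000, seed = 20260919) for k = 3..15;
# regenerate with simulate_ri() to audit.
.ri_table <- c(
  `3` = 0.52275, `4` = 0.88117, `5` = 1.10847, `6` = 1.24790,
  `7` = 1.34061, `8` = 1.40446, `9` = 1.45094, `10` = 1.48549,
  `11` = 1.51315, `12` = 1.53614, `13` = 1.55501, `14` = 1.57003,
  `15` = 1.58378
)

# principal eigenpair of a positive matrix by power iteration
power_eigen <- function(a, tol = 1e-12, maxit = 100000L) {
  k <- nrow(a)
  v <- rep(1 / k, k)
  lam <- 0
  for (it in seq_len(maxit)) {
    w <- drop(a %*% v)
    lam_new <- sum(w) / sum(v)
    w <- w / sum(w)
    if (max(abs(w - v)) < tol && abs(lam_new - lam) < tol) {
      return(list(values = lam_new, vector = w))
    }
    v <- w
    lam <- lam_new
  }
  list(values = lam, vector = v)
}

validate_cm <- function(a, tol = 1e-8) {
  if (is.data.frame(a)) a <- as.matrix(a)
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    stop("a pairwise comparison matrix must be square")
  }
  if (anyNA(a) || any(a <= 0)) stop("all entries must be positive")
  if (any(abs(diag(a) - 1) > tol)) stop("diagonal entries must equal 1")
  if (any(abs(a * t(a) - 1) > tol)) {
    stop("matrix is not reciprocal: a[t, s] must equal 1 / a[s, t]")
  }
  a
}

#' AHP weights and inconsistency indices
#'
#' Derives criterion weights from a `k x k` positive reciprocal pairwise
#' comparison matrix as the (normalized) principal eigenvector, computed by
#' power iteration to tolerance 1e-12, and reports two inconsistency
#' measures:
#' * Saaty's consistency ratio `(lambda_max - k) / ((k - 1) * RI_k)`, where
#'   `RI_k` is the mean random consistency index (bundled simulated table,
#'   see [simulate_ri()]); values below 0.1 are conventionally acceptable;
#' * Koczkodaj's index, the worst relative triad violation
#'   `max over s < t < u of min(|1 - b/(ac)|, |1 - ac/b|)` with
#'   `a = a_st`, `b = a_su`, `c = a_tu`.
#'
#' @param a pairwise comparison matrix (matrix or data frame), entries
#'   `a_st` = strength of preference of criterion s over t.
#' @param ri random index: `NULL` uses the bundled table (3 <= k <= 15), or
#'   supply a positive number.
#' @return an object of class `ahp_result` with `weights`, `lambda_max`,
#'   `saaty`, `koczkodaj`.
#' @examples
#' w <- c(1, 2, 4)
#' ahp_weights(outer(w, w, "/")) # perfectly consistent
#' @export
ahp_weights <- function(a, ri = NULL) {
  a <- validate_cm(a)
  k <- nrow(a)
  if (k < 3L) stop("need at least 3 criteria (no triads below k = 3)")
  if (is.null(ri)) {
    if (!as.character(k) %in% names(.ri_table)) {
      stop("no bundled random index for k = ", k,
           "; pass ri = simulate_ri(", k, ", ...) explicitly")
    }
    ri <- .ri_table[[as.character(k)]]
  }
  pe <- power_eigen(a)
  weights <- pe$vector / sum(pe$vector)
  names(weights) <- rownames(a) %||% paste0("criterion", seq_len(k))
  saaty <- (pe$values - k) / ((k - 1) * ri)
  koc <- 0
  for (s in seq_len(k - 2L)) {
    for (t in seq.int(s + 1L, k - 1L)) {
      for (u in seq.int(t + 1L, k)) {
        x <- a[s, u] / (a[s, t] * a[t, u])
        koc <- max(koc, min(abs(1 - x), abs(1 - 1 / x)))
      }
    }
  }
  structure(
    list(weights = weights, lambda_max = pe$values, saaty = saaty,
         koczkodaj = koc, ri = ri, k = k),
    class = "ahp_result"
  )
}

#' @export
print.ahp_result <- function(x, digits = 4, ...) {
  cat("AHP analysis of a", x$k, "x", x$k, "pairwise comparison matrix\n")
  cat("Weights (principal eigenvector):\n")
  print(round(x$weights, digits))
  cat("lambda_max:", round(x$lambda_max, digits),
      " Saaty CR:", signif(x$saaty, 4),
      " Koczkodaj:", signif(x$koczkodaj, 4), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ahp_result <- function(x, ...) {
  tibble::tibble(criterion = names(x$weights), weight = unname(x$weights))
}

#' @exportS3Method generics::glance
glance.ahp_result <- function(x, ...) {
  tibble::tibble(k = x$k, lambda_max = x$lambda_max, saaty = x$saaty,
                 koczkodaj = x$koczkodaj, ri = x$ri)
}

#' Simulate the AHP random consistency index
#'
#' Estimates `RI_k`, the expected consistency index
#' `(lambda_max - k) / (k - 1)` of a random reciprocal matrix whose
#' upper-triangle entries are drawn uniformly from the 17-point Saaty scale
#' `{1/9, 1/8, ..., 1/2, 1, 2, ..., 9}`.
#'
#' @param k matrix size (>= 3).
#' @param reps number of simulated matrices (>= 100).
#' @param seed RNG seed for reproducibility.
#' @return the Monte-Carlo estimate of `RI_k`.
#' @export
simulate_ri <- function(k, reps = 1000L, seed = NULL) {
  if (k < 3L) stop("k must be at least 3")
  if (reps < 100L) stop("use at least 100 replicates")
  scale_pts <- c(1 / (9:2), 1:9)
  iu <- which(upper.tri(diag(k)), arr.ind = TRUE)
  with_seed(seed, {
    ci <- vapply(seq_len(reps), function(r) {
      a <- matrix(1, k, k)
      v <- sample(scale_pts, nrow(iu), replace = TRUE)
      a[iu] <- v
      a[iu[, 2:1, drop = FALSE]] <- 1 / v
      (power_eigen(a, tol = 1e-10)$values - k) / (k - 1)
    }, numeric(1L))
    mean(ci)
  })
}
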