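# Shared infrastructure for fitted ranking models: the `rank_fit` container,
# exact model probabilities over S_k, Pearson goodness of fit, and
# loglikelihood model selection.

new_rank_fit <- function(family, p, loglik, n_params, extra = list(),
                         gof = NULL) {
  structure(
    c(list(family = family, k = p$k, n = p$N, items = p$items,
           loglik = loglik, n_params = n_params, gof = gof),
      extra),
    class = "rank_fit"
  )
}

#' Exact probability of every ranking under a fitted model
#'
#' Enumerates S_k and returns the model probability of each ranking, in the
#' row order of [permutations_of()]. Probabilities sum to one by
#' construction. Only available for models whose probabilities do not
#' depend on judge covariates (i.e. not rank-ordered logit).
#'
#' @param fit a `rank_fit` object.
#' @return numeric vector of length `factorial(k)`.
#' @export
model_probs <- function(fit) {
  stopifnot(inherits(fit, "rank_fit"))
  k <- fit$k
  switch(
    fit$family,
    luce = probs_luce(fit$utilities, k),
    dbm = probs_dbm(fit$pi0, fit$lambda, fit$dtype),
    phicom = probs_phicom(fit$pi0, fit$lambdas),
    wdbm = probs_wdbm(fit$pi0, fit$weights, fit$dtype),
    stop("exact ranking probabilities are not defined for family '",
         fit$family, "'")
  )
}

probs_luce <- function(v, k) {
  perms <- permutations_of(k)
  ords <- t(apply(perms, 1L, order))
  logV <- matrix(log(v), nrow(perms), k, byrow = TRUE)
  exp(pl_loglik_rows(logV, ords))
}

probs_dbm <- function(pi0, lambda, dtype, weights = NULL) {
  perms <- permutations_of(length(pi0))
  d <- dist_many(perms, pi0, dtype, weights)
  lp <- -lambda * d
  exp(lp - logsumexp(lp))
}

probs_phicom <- function(pi0, lambdas) {
  perms <- permutations_of(length(pi0))
  V <- stage_counts_many(perms, pi0)
  lp <- -drop(V %*% lambdas)
  exp(lp - logsumexp(lp))
}

probs_wdbm <- function(pi0, w, dtype) {
  perms <- permutations_of(length(pi0))
  d <- dist_many(perms, pi0, dtype, w)
  exp(-d - logsumexp(-d))
}

#' Pearson goodness of fit of a ranking model
#'
#' Compares observed ranking frequencies with the expected frequencies
#' `E_i = N * P(pi_i)` over all `k!` rankings via the sum of squared
#' Pearson residuals `chi2 = sum_i (O_i - E_i)^2 / E_i` (unobserved
#' rankings contribute with `O_i = 0`). Degrees of freedom are
#' `k! - 1 - n_params`, the conventional count after estimating the model's
#' free parameters.
#'
#' @param x the ranking table the model was fitted to.
#' @param fit a `rank_fit` whose exact probabilities are available, or a
#'   bare probability vector over all `k!` rankings (in [permutations_of()]
#'   row order; counted as zero estimated parameters).
#' @return list with `chi2`, `df` and `p.value`.
#' @export
goodness_of_fit <- function(x, fit) {
  p <- rt_parts(x, allow_ties = FALSE)
  if (is.numeric(fit)) {
    if (length(fit) != factorial(p$k)) {
      stop("probability vector must cover all k! rankings")
    }
    probs <- fit
    fit <- list(n_params = 0L)
  } else {
    probs <- model_probs(fit)
  }
  E <- p$N * probs
  if (any(E == 0)) {
    stop("some expected frequencies are exactly zero; Pearson residuals ",
         "are undefined")
  }
  O <- ranking_counts(p)
  chi2 <- sum((O - E)^2 / E)
  df <- factorial(p$k) - 1L - fit$n_params
  list(chi2 = chi2, df = df,
       p.value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

# GOF used inside fitting: degrade to NULL (with a warning) when expected
# counts underflow to zero rather than failing the whole fit.
gof_or_null <- function(p, probs, n_params) {
  E <- p$N * probs
  if (any(E == 0)) {
    warning("expected frequencies underflow to zero for some rankings; ",
            "goodness of fit not computed")
    return(NULL)
  }
  O <- ranking_counts(p)
  chi2 <- sum((O - E)^2 / E)
  df <- factorial(p$k) - 1L - n_params
  list(chi2 = chi2, df = df,
       p.value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Select the best-fitting ranking model by loglikelihood
#'
#' @param ... fitted `rank_fit` objects, or a single list of them.
#' @return the fit with the largest loglikelihood; the full comparison table
#'   is attached as attribute `"comparison"` and shown by `print()`.
#' @export
select_model <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "rank_fit")) {
    fits <- fits[[1L]]
  }
  if (length(fits) == 0L) stop("no fitted models supplied")
  stopifnot(all(vapply(fits, inherits, logical(1L), "rank_fit")))
  tab <- dplyr::bind_rows(lapply(fits, glance))
  best <- fits[[which.max(tab$logLik)]]
  attr(best, "comparison") <- tab
  best
}

#' @export
print.rank_fit <- function(x, digits = 4, ...) {
  lab <- switch(x$family,
                luce = "Luce (Plackett-Luce) model",
                rol = "Rank-ordered logit model",
                dbm = paste0("Distance-based model (", x$dtype, ")"),
                phicom = "Phi-component model",
                wdbm = paste0("Weighted distance-based model (", x$dtype, ")"),
                x$family)
  cat(lab, "fitted to", x$n, "rankings of", x$k, "items\n")
  if (!is.null(x$pi0)) {
    cat("Modal ranking: (", paste(x$pi0, collapse = ", "), ")\n", sep = "")
  }
  if (!is.null(x$utilities)) {
    cat("Utilities (reference item = 1):\n")
    print(round(x$utilities, digits))
  }
  if (!is.null(x$lambda)) cat("Dispersion lambda:", round(x$lambda, digits), "\n")
  if (!is.null(x$lambdas)) {
    cat("Stage dispersions:\n")
    print(round(x$lambdas, digits))
  }
  if (!is.null(x$weights) && x$family == "wdbm") {
    cat("Rank-position weights:\n")
    print(round(x$weights, digits))
  }
  if (!is.null(x$coef) && is.data.frame(x$coef)) {
    cat("Coefficients:\n")
    print(x$coef, n = Inf)
  }
  cat("logLik:", round(x$loglik, digits), " (", x$n_params, "parameters )\n")
  if (!is.null(x$gof)) {
    cat("Goodness of fit: chi2 =", round(x$gof$chi2, digits),
        "on", x$gof$df, "df, p =", signif(x$gof$p.value, 3), "\n")
  }
  cmp <- attr(x, "comparison")
  if (!is.null(cmp)) {
    cat("\nModel comparison (selected by largest logLik):\n")
    print(cmp)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rank_fit <- function(x, ...) {
  if (!is.null(x$coef) && is.data.frame(x$coef)) return(tibble::as_tibble(x$coef))
  rows <- list()
  if (!is.null(x$utilities)) {
    rows <- c(rows, list(tibble::tibble(term = paste0("utility[", x$items, "]"),
                                        estimate = unname(x$utilities))))
  }
  if (!is.null(x$pi0)) {
    rows <- c(rows, list(tibble::tibble(term = paste0("pi0[", x$items, "]"),
                                        estimate = as.numeric(x$pi0))))
  }
  if (!is.null(x$lambda)) {
    rows <- c(rows, list(tibble::tibble(term = "lambda", estimate = x$lambda)))
  }
  if (!is.null(x$lambdas)) {
    rows <- c(rows, list(tibble::tibble(
      term = paste0("lambda", seq_along(x$lambdas)),
      estimate = unname(x$lambdas))))
  }
  if (!is.null(x$weights) && x$family == "wdbm") {
    rows <- c(rows, list(tibble::tibble(
      term = paste0("w", seq_along(x$weights)),
      estimate = unname(x$weights))))
  }
  dplyr::bind_rows(rows)
}

#' @exportS3Method generics::glance
glance.rank_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    dtype = x$dtype %||% NA_character_,
    logLik = x$loglik,
    n_params = x$n_params,
    gof_chi2 = if (is.null(x$gof)) NA_real_ else x$gof$chi2,
    gof_df = if (is.null(x$gof)) NA_integer_ else x$gof$df,
    gof_p = if (is.null(x$gof)) NA_real_ else x$gof$p.value,
    nobs = x$n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rank_fit <- function(object, ...) {
  if (object$family == "rol") {
    stop("autoplot is not available for rank-ordered logit fits; ",
         "plot tidy(fit) instead")
  }
  probs <- model_probs(object)
  perms <- permutations_of(object$k)
  df <- tibble::tibble(
    ranking = apply(perms, 1L, paste, collapse = ""),
    probability = probs
  )
  df <- df[order(-df$probability), ]
  df$ranking <- factor(df$ranking, levels = df$ranking)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ranking, y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ranking (ranks of items 1..k)",
                  y = "model probability") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
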