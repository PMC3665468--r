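# Local k-nearest-neighbour label ranking: predict a new judge's ranking
# by fitting a Luce model to the rankings of the judge's nearest
# neighbours in covariate space and ordering the items by fitted utility.

# order items by decreasing utility -> predicted ranking (ties by index)
utilities_to_ranking <- function(u) rank(-u, ties.method = "first")

# mean-rank fallback ordering for degenerate neighbourhoods
mean_rank_prediction <- function(R, freq = rep(1, nrow(R))) {
  utilities_to_ranking(-colSums(R * freq) / sum(freq))
}

# Luce-based prediction for one neighbourhood of individual rankings;
# falls back to the mean-rank ordering when the fit degenerates (boundary
# estimates or optimizer failure), which is common for tiny neighbourhoods
# where some item is never ranked above another.
predict_neighbourhood <- function(R) {
  pred <- tryCatch({
    fit <- suppressWarnings(fit_luce(as.data.frame(R)))
    if (isTRUE(fit$boundary)) NULL else utilities_to_ranking(fit$utilities)
  }, error = function(e) NULL)
  pred %||% mean_rank_prediction(R)
}

#' Local k-nearest-neighbour label ranking
#'
#' For each test judge, selects the `knn_k` training judges nearest in
#' Euclidean distance on the covariates (distance ties broken by training
#' row index), fits a Luce model to their rankings, and predicts the
#' ranking that orders items by decreasing fitted utility. Neighbourhoods
#' on which the Luce fit degenerates fall back to the neighbourhood's
#' mean-rank ordering.
#'
#' Covariates are used as given (Euclidean distance is scale sensitive);
#' set `standardize = TRUE` to z-score each covariate by its training mean
#' and standard deviation first.
#'
#' @param train_rankings `N x k` individual ranking table.
#' @param train_cov,test_cov numeric covariate tables (`N x M`, `T x M`).
#' @param knn_k neighbourhood size, `1 <= knn_k <= N`.
#' @param standardize z-score covariates using training statistics.
#' @return tibble of `T` predicted rankings.
#' @export
local_knn <- function(train_rankings, train_cov, test_cov, knn_k,
                      standardize = FALSE) {
  p <- rt_parts(train_rankings, allow_ties = FALSE)
  if (any(p$freq != 1)) stop("train_rankings must be individual rankings")
  Xtr <- as.matrix(as.data.frame(train_cov))
  Xte <- as.matrix(as.data.frame(test_cov))
  if (!is.numeric(Xtr) || !is.numeric(Xte)) stop("covariates must be numeric")
  if (nrow(Xtr) != nrow(p$R)) stop("train_cov must have one row per judge")
  if (ncol(Xte) != ncol(Xtr)) stop("test_cov has a different covariate count")
  if (knn_k < 1L || knn_k > nrow(Xtr)) stop("knn_k must be in 1..N")
  if (standardize) {
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2L, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sd, "/")
    Xte <- sweep(sweep(Xte, 2L, mu), 2L, sd, "/")
  }
  preds <- matrix(0L, nrow(Xte), p$k)
  for (t in seq_len(nrow(Xte))) {
    d2 <- colSums((t(Xtr) - Xte[t, ])^2)
    nb <- order(d2, seq_along(d2))[seq_len(knn_k)]
    preds[t, ] <- predict_neighbourhood(p$R[nb, , drop = FALSE])
  }
  colnames(preds) <- p$items
  tibble::as_tibble(as.data.frame(preds))
}

#' Cross-validated neighbourhood size for local label ranking
#'
#' Chooses `knn_k` by seeded `folds`-fold cross-validation on the training
#' data: for every candidate in `k_grid` the CV error is the total Kendall
#' tau distance between the predicted and observed rankings of held-out
#' judges, and the smallest candidate attaining the minimum wins. Judges
#' are assigned to folds by a seeded shuffle (any remainder spread over the
#' first folds). A fold whose prediction fails outright is penalized with
#' the maximum distance `choose(k, 2)` per judge. Final predictions for
#' `test_cov` use the winning neighbourhood size on the full training set.
#'
#' @inheritParams local_knn
#' @param folds number of cross-validation folds (default 10).
#' @param k_grid candidate neighbourhood sizes (default 1..20).
#' @param seed RNG seed for the fold shuffle.
#' @return an object of class `local_knn_cv`: `best_k`, `cv_error`
#'   (tibble of candidate k and total Kendall error) and `predictions`.
#' @export
local_knn_cv <- function(train_rankings, train_cov, test_cov, folds = 10L,
                         k_grid = 1:20, seed = NULL, standardize = FALSE) {
  p <- rt_parts(train_rankings, allow_ties = FALSE)
  n <- nrow(p$R)
  if (folds < 2L) stop("need at least 2 folds")
  if (n < folds) stop("fewer judges than folds")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  train_df <- tibble::as_tibble(as.data.frame(p$R))
  names(train_df) <- p$items
  cov_df <- as.data.frame(train_cov)
  err <- vapply(k_grid, function(kk) {
    tot <- 0
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      kk_use <- min(kk, sum(!hold))
      pred <- tryCatch(
        local_knn(train_df[!hold, , drop = FALSE],
                  cov_df[!hold, , drop = FALSE],
                  cov_df[hold, , drop = FALSE],
                  knn_k = kk_use, standardize = standardize),
        error = function(e) NULL
      )
      tot <- tot + if (is.null(pred)) {
        sum(hold) * choose(p$k, 2)
      } else {
        pm <- as.matrix(pred)
        ob <- p$R[hold, , drop = FALSE]
        sum(vapply(seq_len(nrow(pm)), function(i) {
          rank_distance(pm[i, ], ob[i, ], "tau")
        }, numeric(1L)))
      }
    }
    tot
  }, numeric(1L))
  best_k <- k_grid[which.min(err)] # which.min takes the smallest index on ties
  structure(
    list(best_k = best_k,
         cv_error = tibble::tibble(k = k_grid, error = err),
         predictions = local_knn(train_df, cov_df, test_cov, knn_k = best_k,
                                 standardize = standardize),
         folds = folds, seed = seed),
    class = "local_knn_cv"
  )
}

#' @export
print.local_knn_cv <- function(x, ...) {
  cat("Local kNN label ranking,", x$folds, "-fold cross-validation\n")
  cat("Best neighbourhood size k =", x$best_k,
      "(total Kendall CV error ", x$cv_error$error[x$cv_error$k == x$best_k],
      ")\n")
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.local_knn_cv <- function(object, ...) {
  ggplot2::ggplot(object$cv_error,
                  ggplot2::aes(x = .data$k, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = 2) +
    ggplot2::labs(x = "neighbourhood size k",
                  y = "total Kendall CV error")
}
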