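# Multidimensional preference analysis (MDPREF): an SVD biplot of the
# judge-by-item matrix of centered ranks. Judges become vectors, items
# points; the projection of the item points onto a judge's vector
# approximates that judge's ranking when the retained dimensions explain
# the data well.

#' Multidimensional preference analysis of ranking data
#'
#' Centers the `N x k` rank matrix by the overall mean rank `(k + 1) / 2`
#' and takes its singular value decomposition `X = U D V'`. Judges are
#' represented by the first `d` columns of `sqrt(N - 1) * U`, items by the
#' first `d` columns of `V D / sqrt(N - 1)`; with all dimensions retained
#' `judge_coords %*% t(item_coords)` reconstructs `X` exactly. The
#' proportion of variance carried by dimension `m` is
#' `D_mm^2 / sum(D^2)`. Signs are fixed deterministically (the largest
#' absolute item loading of each dimension is made positive).
#'
#' @param x individual or aggregated ranking table (aggregated tables are
#'   expanded to one row per judge); mean-rank imputed ties are accepted.
#' @param d number of dimensions to retain (default 2).
#' @return an object of class `mdpref` with `item_coords` (`k x d`),
#'   `judge_coords` (`N x d`), `explain` (variance proportions over all
#'   dimensions), `d`, `n`, `k`.
#' @examples
#' m <- mdpref(sample_luce(c(4, 2, 1, 1), 50, seed = 1))
#' m$explain
#' @export
mdpref <- function(x, d = 2L) {
  p <- rt_parts(x, allow_ties = TRUE)
  R <- p$R[rep(seq_along(p$freq), p$freq), , drop = FALSE]
  N <- nrow(R)
  k <- p$k
  if (N < 2L) stop("need at least two judges")
  d <- as.integer(d)
  if (d < 1L || d > min(N, k)) stop("d must be between 1 and min(N, k)")
  X <- R - (k + 1) / 2
  if (all(abs(X) < 1e-12)) stop("no variance: all centered ranks are zero")
  sv <- svd(X)
  # deterministic sign: largest |item loading| per dimension made positive
  for (m in seq_along(sv$d)) {
    j <- which.max(abs(sv$v[, m]))
    if (sv$v[j, m] < 0) {
      sv$v[, m] <- -sv$v[, m]
      sv$u[, m] <- -sv$u[, m]
    }
  }
  explain <- sv$d^2 / sum(sv$d^2)
  judge <- sqrt(N - 1) * sv$u
  item <- sv$v %*% diag(sv$d, length(sv$d)) / sqrt(N - 1)
  dimnames(item) <- list(p$items, paste0("dim", seq_along(sv$d)))
  colnames(judge) <- paste0("dim", seq_along(sv$d))
  structure(
    list(item_coords = item[, seq_len(d), drop = FALSE],
         judge_coords = judge[, seq_len(d), drop = FALSE],
         explain = explain, d = d, n = N, k = k, items = p$items),
    class = "mdpref"
  )
}

#' @export
print.mdpref <- function(x, digits = 4, ...) {
  cat("Multidimensional preference analysis:", x$n, "judges,", x$k,
      "items,", x$d, "dimensions retained\n")
  cat("Variance explained by retained dimensions:",
      paste0(round(100 * x$explain[seq_len(x$d)], 1), "%", collapse = ", "),
      "(total ", round(100 * sum(x$explain[seq_len(x$d)]), 1), "%)\n")
  cat("\nItem coordinates:\n")
  print(round(x$item_coords, digits))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mdpref <- function(x, ...) {
  it <- tibble::as_tibble(as.data.frame(x$item_coords))
  it <- dplyr::mutate(it, label = x$items, role = "item", .before = 1L)
  jd <- tibble::as_tibble(as.data.frame(x$judge_coords))
  jd <- dplyr::mutate(jd, label = paste0("judge", seq_len(x$n)),
                      role = "judge", .before = 1L)
  dplyr::bind_rows(it, jd)
}

#' @exportS3Method generics::glance
glance.mdpref <- function(x, ...) {
  tibble::tibble(n_judges = x$n, k = x$k, d = x$d,
                 explained = sum(x$explain[seq_len(x$d)]))
}

#' Preference biplot
#'
#' Plots the first two MDPREF dimensions: items as labeled points, judges
#' as vectors from the origin. For display only, judge vectors are scaled
#' by a common factor so that the longest matches the most distant item;
#' the coordinates stored in the object are never rescaled.
#'
#' @param object an `mdpref` object (needs `d >= 2`).
#' @param scale_judges rescale judge vectors for display (default TRUE).
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mdpref <- function(object, scale_judges = TRUE, ...) {
  if (object$d < 2L) stop("need at least two retained dimensions to plot")
  it <- as.data.frame(object$item_coords[, 1:2, drop = FALSE])
  names(it) <- c("x", "y")
  it$label <- object$items
  jd <- as.data.frame(object$judge_coords[, 1:2, drop = FALSE])
  names(jd) <- c("x", "y")
  if (scale_judges) {
    r_it <- max(sqrt(it$x^2 + it$y^2))
    r_jd <- max(sqrt(jd$x^2 + jd$y^2))
    if (r_jd > 0) jd[, c("x", "y")] <- jd[, c("x", "y")] * r_it / r_jd
  }
  pct <- round(100 * object$explain[1:2], 1)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = jd,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          alpha = 0.25) +
    ggplot2::geom_point(data = it, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::geom_text(data = it,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       vjust = -0.8) +
    ggplot2::labs(x = paste0("dimension 1 (", pct[1], "%)"),
                  y = paste0("dimension 2 (", pct[2], "%)"),
                  title = "Multidimensional preference map")
}
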