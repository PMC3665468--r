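# Core data model: rankings, orderings, aggregated ranking tables,
# partial-ranking imputation and descriptive statistics.
#
# A ranking assigns rank pi(i) to item i (1 = most preferred). An ordering
# is the inverse map: entry j is the item holding rank j. Data frames carry
# one column per item; an aggregated table additionally carries a trailing
# frequency column named "n" (one row per distinct ranking).

# Decompose an individual or aggregated ranking data frame into its parts.
# Detection rule: a final column named "n" marks the aggregated format.
rt_parts <- function(x, allow_ties = FALSE, what = "rankings") {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop(what, " must be a data frame or matrix")
  if (nrow(x) == 0L) stop("no rankings")
  nm <- names(x)
  aggregated <- length(nm) > 1L && nm[length(nm)] == "n"
  if (aggregated) {
    freq <- x[[length(nm)]]
    rk <- as.matrix(x[, -length(nm), drop = FALSE])
    if (anyNA(freq) || any(freq < 0) || any(freq != round(freq))) {
      stop("frequency column 'n' must contain nonnegative integers")
    }
    keep <- freq > 0
    rk <- rk[keep, , drop = FALSE]
    freq <- as.numeric(freq[keep])
    if (nrow(rk) == 0L) stop("no rankings (all frequencies zero)")
  } else {
    rk <- as.matrix(x)
    freq <- rep(1, nrow(rk))
  }
  if (!is.numeric(rk)) stop(what, " must be numeric")
  k <- ncol(rk)
  if (k < 2L) stop("need at least two items")
  bad <- which(!apply(rk, 1L, if (allow_ties) is_ranking else is_permutation))
  if (length(bad)) {
    stop(what, ": row ", bad[1L], " is not a ",
         if (allow_ties) "complete ranking (positive ranks summing to k(k+1)/2)"
         else "permutation of 1..k",
         ": (", paste(rk[bad[1L], ], collapse = ", "), ")")
  }
  list(R = rk, freq = freq, k = k, N = sum(freq),
       items = colnames(rk) %||% paste0("item", seq_len(k)))
}

#' Aggregate individual rankings into a frequency table
#'
#' Collapses an `N x k` table of individual rankings (one row per judge,
#' entry = rank given to the item in that column) into the aggregated format:
#' one row per distinct ranking plus a frequency column `n`, sorted
#' lexicographically by ranks.
#'
#' @param x data frame or matrix of individual rankings, one column per item.
#' @param allow_ties accept mean-rank imputed (tied, non-integer) rankings.
#' @return a tibble with the `k` item columns and a trailing `n` column;
#'   `sum(n)` equals `nrow(x)`.
#' @examples
#' rank_agg(data.frame(a = c(1, 1, 2), b = c(2, 2, 1), c = c(3, 3, 3)))
#' @export
rank_agg <- function(x, allow_ties = FALSE) {
  p <- rt_parts(x, allow_ties = allow_ties)
  df <- tibble::as_tibble(as.data.frame(p$R))
  names(df) <- p$items
  out <- dplyr::count(df, dplyr::across(dplyr::everything()), name = "n")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(p$items)))
}

#' Expand an aggregated ranking table back to individual rankings
#'
#' @param tab aggregated table (item columns plus frequency column `n`).
#' @return tibble with one row per judge.
#' @export
rank_expand <- function(tab) {
  p <- rt_parts(tab, allow_ties = TRUE)
  df <- tibble::as_tibble(as.data.frame(p$R[rep(seq_along(p$freq), p$freq), ,
                                            drop = FALSE]))
  names(df) <- p$items
  df
}

#' Convert a ranking to its ordering (and back)
#'
#' `ranking_to_ordering()` inverts a complete ranking: entry `j` of the
#' result is the item holding rank `j`. `ordering_to_ranking()` is the
#' inverse operation. Both are involutions in the sense that composing the
#' two is the identity.
#'
#' @param ranks complete (untied) ranking vector.
#' @param items ordering vector (a permutation of item indices).
#' @return an integer permutation vector of the same length.
#' @examples
#' ranking_to_ordering(c(2, 3, 1)) # items by rank: 3, 1, 2
#' @export
ranking_to_ordering <- function(ranks) {
  if (!is_permutation(ranks)) {
    if (is_ranking(ranks)) stop("ordering undefined for ties")
    stop("not a complete ranking of 1..k")
  }
  order(ranks)
}

#' @rdname ranking_to_ordering
#' @export
ordering_to_ranking <- function(items) {
  if (!is_permutation(items)) stop("not a permutation of item indices")
  ranks <- integer(length(items))
  ranks[items] <- seq_along(items)
  ranks
}

#' Impute a partial ranking by the mean of the unassigned ranks
#'
#' A partial ranking assigns ranks `1..t` to `t < k` items and leaves the
#' rest missing (`NA`). Every missing entry receives the mean of the unused
#' ranks `{t+1, ..., k}`, so the completed ranking still sums to
#' `k(k+1)/2`. This is the standard treatment for "rank your top t" data.
#'
#' @param partial numeric vector with `NA` for unranked items.
#' @return completed numeric ranking (possibly with tied non-integer ranks).
#' @examples
#' impute_partial(c(1, 2, 3, 4, 5, NA, NA)) # -> 6.5 for both missing
#' @export
impute_partial <- function(partial) {
  k <- length(partial)
  miss <- is.na(partial)
  if (!any(miss)) return(partial)
  assigned <- sort(partial[!miss])
  t <- length(assigned)
  if (!isTRUE(all.equal(assigned, as.numeric(seq_len(t))))) {
    stop("assigned ranks must form the prefix 1..t (got: ",
         paste(assigned, collapse = ", "), ")")
  }
  out <- as.numeric(partial)
  out[miss] <- mean(seq.int(t + 1L, k))
  out
}

#' Descriptive statistics of a ranking dataset
#'
#' Computes, from an individual or aggregated ranking table:
#' * the mean rank of each item, `m_j = (1/N) sum_i N_i pi_i(j)`;
#' * the `k x k` pair matrix `P`, whose `(s, t)` entry counts the judges for
#'   whom `pi(s) > pi(t)` (with `direction = "rank_exceeds"`, the default) or
#'   `pi(s) < pi(t)` (`direction = "beats"`, i.e. s preferred over t);
#' * the `k x k` marginal matrix `M`, whose `(s, t)` entry counts the judges
#'   ranking item `s` in position `t`.
#'
#' Pair and marginal matrices are only defined for strict integer rankings;
#' with mean-rank imputed ties they are dropped with a warning and only the
#' mean ranks are returned.
#'
#' @param x individual or aggregated ranking table.
#' @param direction pair-matrix convention, see above.
#' @return an object of class `rank_descriptives` with fields `mean_rank`
#'   (named numeric), `pair`, `marginal` (matrices or `NULL`), `n`, `k`.
#' @examples
#' destat(data.frame(a = c(1, 1), b = c(2, 2), c = c(3, 3)))
#' @export
destat <- function(x, direction = c("rank_exceeds", "beats")) {
  direction <- match.arg(direction)
  p <- rt_parts(x, allow_ties = TRUE)
  mean_rank <- colSums(p$R * p$freq) / p$N
  names(mean_rank) <- p$items
  strict <- all(apply(p$R, 1L, is_permutation))
  pair <- marginal <- NULL
  if (strict) {
    k <- p$k
    pair <- matrix(0, k, k, dimnames = list(p$items, p$items))
    marginal <- matrix(0, k, k,
                       dimnames = list(p$items, paste0("rank", seq_len(k))))
    for (s in seq_len(k)) {
      for (t in seq_len(k)) {
        if (s != t) {
          cmp <- if (direction == "rank_exceeds") p$R[, s] > p$R[, t]
                 else p$R[, s] < p$R[, t]
          pair[s, t] <- sum(p$freq[cmp])
        }
        marginal[s, t] <- sum(p$freq[abs(p$R[, s] - t) < 1e-9])
      }
    }
  } else {
    warning("tied (imputed) rankings present: pair and marginal matrices ",
            "are not defined and were omitted")
  }
  structure(
    list(mean_rank = mean_rank, pair = pair, marginal = marginal,
         n = p$N, k = p$k, direction = direction),
    class = "rank_descriptives"
  )
}

#' @export
print.rank_descriptives <- function(x, digits = 4, ...) {
  cat("Descriptive statistics for", x$n, "rankings of", x$k, "items\n\n")
  cat("Mean ranks:\n")
  print(round(x$mean_rank, digits))
  if (!is.null(x$pair)) {
    cat("\nPair matrix (entry [s, t] = #judges with ",
        if (x$direction == "rank_exceeds") "rank(s) > rank(t)"
        else "s preferred over t", "):\n", sep = "")
    print(x$pair)
    cat("\nMarginal matrix (entry [s, t] = #judges ranking item s in position t):\n")
    print(x$marginal)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rank_descriptives <- function(x, ...) {
  tibble::tibble(item = names(x$mean_rank), mean_rank = unname(x$mean_rank))
}

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.rank_descriptives <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$item, levels = df$item[order(df$mean_rank)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$mean_rank)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = (object$k + 1) / 2, linetype = 2) +
    ggplot2::labs(x = NULL, y = "mean rank",
                  caption = "dashed line: uniform expectation (k+1)/2") +
    ggplot2::coord_flip()
}
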