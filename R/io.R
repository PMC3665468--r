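# CSV input/output for ranking tables, covariates and comparison matrices.
# Individual format: header of item names, one row per judge, ranks as
# entries. Aggregated format: the same item columns plus a trailing
# frequency column named "n".

#' Read a ranking table from CSV
#'
#' @param path CSV file with a header row of item names.
#' @param mode `"individual"` (one row per judge) or `"aggregated"`
#'   (distinct rankings plus a trailing frequency column `n`).
#' @param allow_ties accept mean-rank imputed (non-integer, tied) rankings.
#' @return a tibble in the requested format, validated row by row.
#' @export
read_rankings <- function(path, mode = c("individual", "aggregated"),
                          allow_ties = FALSE) {
  mode <- match.arg(mode)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (mode == "aggregated") {
    if (!"n" %in% names(df) || names(df)[ncol(df)] != "n") {
      stop("aggregated file must end with a frequency column named 'n': ",
           path)
    }
  } else if ("n" %in% names(df)) {
    stop("individual file must not contain a column named 'n': ", path)
  }
  bad <- which(!vapply(df, is.numeric, logical(1L)))
  if (length(bad)) {
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(df)[bad], collapse = ", "))
  }
  rt_parts(df, allow_ties = allow_ties, what = paste0("file ", path))
  tibble::as_tibble(df)
}

#' Write a ranking table to CSV
#'
#' @param x individual or aggregated ranking table.
#' @param path output file.
#' @return `x`, invisibly.
#' @export
write_rankings <- function(x, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(x)
}

#' Read a pairwise comparison matrix from CSV
#'
#' The file holds the `k x k` matrix entries (header row of criterion
#' names, no row-name column).
#'
#' @param path CSV file.
#' @return validated comparison matrix with criterion names.
#' @export
read_comparison_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  a <- as.matrix(df)
  rownames(a) <- colnames(a)
  validate_cm(a)
}
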