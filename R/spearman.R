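#' Spearman correlation between the rows of two profile matrices
#'
#' Columns (conditions) are matched by name; each pair of rows is correlated
#' with Spearman's rank correlation using average ranks for ties and
#' pairwise-complete deletion of missing conditions.  Pairs with fewer than
#' `min_overlap` shared finite conditions are `NA`.
#'
#' @param a,b Numeric matrices (rows = elements, columns = shared conditions).
#' @param min_overlap Minimum number of shared finite conditions (default 3).
#' @return `nrow(a)` x `nrow(b)` correlation matrix.
#' @export
cross_spearman <- function(a, b, min_overlap = 3L) {
  a <- as.matrix(unclass(a)); b <- as.matrix(unclass(b))
  common <- intersect(colnames(a), colnames(b))
  if (length(common) < min_overlap) {
    stop("fewer than ", min_overlap, " shared conditions", call. = FALSE)
  }
  a <- a[, common, drop = FALSE]
  b <- b[, common, drop = FALSE]
  if (!anyNA(a) && !anyNA(b)) {
    # complete data: rank rows once, then Pearson on the ranks
    ra <- t(apply(a, 1, rank))
    rb <- t(apply(b, 1, rank))
    return(suppressWarnings(stats::cor(t(ra), t(rb))))
  }
  out <- matrix(NA_real_, nrow(a), nrow(b),
                dimnames = list(rownames(a), rownames(b)))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      x <- a[i, ]; y <- b[j, ]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_overlap) next
      out[i, j] <- suppressWarnings(
        stats::cor(x[ok], y[ok], method = "spearman")
      )
    }
  }
  out
}

#' Spearman co-fitness (or co-expression) matrix
#'
#' Pairwise Spearman correlation of the profile vectors of a set of
#' elements; the *co-fitness* of two genes is the correlation of their
#' fitness vectors across conditions.
#'
#' @param matrix A [profile_matrix] (or named matrix) with >= 2 rows.
#' @param min_overlap Minimum shared finite conditions per pair (default 3).
#' @return Symmetric correlation matrix with unit diagonal; pairs failing
#'   the overlap requirement are `NA`.
#' @export
cofitness_matrix <- function(matrix, min_overlap = 3L) {
  m <- as.matrix(unclass(matrix))
  if (nrow(m) < 2) stop("need at least 2 elements", call. = FALSE)
  out <- cross_spearman(m, m, min_overlap = min_overlap)
  out <- (out + t(out)) / 2  # enforce exact symmetry
  diag(out) <- 1
  out
}
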