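#' Element-by-condition profile matrices
#'
#' Fitness and expression screens are held as a numeric matrix with element
#' ids (genes, promoters/regions, or reactions) on the rows and condition ids
#' on the columns.  Missing measurements stay `NA` and are never imputed; a
#' `normalized` attribute records whether columns have been Z-scored.
#'
#' @param values Numeric matrix with unique row and column names.
#' @param normalized Logical flag, `TRUE` after [z_normalize()].
#' @return A `profile_matrix` (a plain matrix subclass).
#' @export
profile_matrix <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("profile matrix needs row and column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate row ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate condition ids", call. = FALSE)
  structure(values, normalized = isTRUE(normalized),
            class = c("profile_matrix", "matrix", "array"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x), " x ", ncol(x),
      if (is_normalized(x)) " (Z-normalized)" else " (raw)", "\n", sep = "")
  print(utils::head(unclass(x), 4))
  invisible(x)
}

#' @rdname profile_matrix
#' @param x A `profile_matrix`.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @export
as_tibble.profile_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame(unclass(x)), rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "condition", values_to = "value")
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Z-normalize a profile matrix per condition
#'
#' Each column is centred and scaled over its finite entries using the
#' population standard deviation (divide by N, the size of the considered
#' set).  Missing entries are preserved.
#'
#' @param matrix A [profile_matrix] (or plain named matrix).
#' @return A normalized [profile_matrix].
#' @export
z_normalize <- function(matrix) {
  m <- if (inherits(matrix, "profile_matrix")) matrix else profile_matrix(matrix)
  vals <- unclass(m)
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    ok <- is.finite(x)
    if (sum(ok) < 2) {
      stop("condition '", colnames(vals)[j],
           "' has fewer than 2 finite values", call. = FALSE)
    }
    mu <- mean(x[ok])
    sigma <- sqrt(mean((x[ok] - mu)^2))
    if (sigma == 0) {
      stop("condition '", colnames(vals)[j], "' has zero spread",
           call. = FALSE)
    }
    vals[, j] <- (x - mu) / sigma
  }
  profile_matrix(vals, normalized = TRUE)
}

#' Difference of one element's scores between two conditions
#'
#' Used to contrast a pair of media conditions for a promoter or gene: a
#' positive value means the element fares better under the first condition.
#'
#' @param matrix A [profile_matrix].
#' @param elem Row id.
#' @param cond_a,cond_b Condition (column) ids; the score is
#'   `value[elem, cond_a] - value[elem, cond_b]`.
#' @return A single number, `NA` if either entry is missing.
#' @export
condition_pair_score <- function(matrix, elem, cond_a, cond_b) {
  stopifnot(inherits(matrix, "profile_matrix"))
  if (!elem %in% rownames(matrix)) stop("unknown element: ", elem, call. = FALSE)
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% colnames(matrix)) stop("unknown condition: ", cc, call. = FALSE)
  }
  unname(matrix[elem, cond_a] - matrix[elem, cond_b])
}

#' Extract aligned per-element profile vectors
#'
#' @param matrix A [profile_matrix].
#' @param ids Row ids to extract.
#' @return Named list of condition-named numeric vectors, in the matrix's
#'   condition order.
#' @export
build_vectors <- function(matrix, ids) {
  stopifnot(inherits(matrix, "profile_matrix"))
  missing <- setdiff(ids, rownames(matrix))
  if (length(missing) > 0) {
    stop("unknown id(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(ids, function(i) matrix[i, ])
  names(out) <- ids
  out
}

# --- readers ---------------------------------------------------------------

#' Read a gene-by-condition fitness (or expression) TSV
#'
#' First column: element id; remaining columns: one per condition, numeric
#' scores with empty cells or `NA` for missing measurements.
#'
#' @param path TSV path.
#' @return A raw (un-normalized) [profile_matrix].
#' @export
read_profile_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) stop("profile table needs id + >=1 condition", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  profile_matrix(vals)
}

#' Write a profile matrix as TSV
#' @param matrix A [profile_matrix].
#' @param path Output path.
#' @param id_col Name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(matrix, path, id_col = "id") {
  df <- tibble::as_tibble(as.data.frame(unclass(matrix)), rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a per-insertion fitness table
#'
#' Expected columns: `position` (0-based genomic coordinate), `scaffold`
#' (sequence name), then one numeric column per condition.
#'
#' @param path TSV path.
#' @return A tibble with `position`, `scaffold` and condition columns.
#' @export
read_insertion_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("position", "scaffold") %in% names(df)))
  if (any(df$position < 0)) stop("negative insertion position", call. = FALSE)
  tibble::as_tibble(df)
}

#' Read a genomic region annotation table
#'
#' A BED-like TSV with header and columns `scaffold`, `start`, `end`
#' (0-based half-open), `id`, `kind` (one of `promoter`, `five_prime_utr`,
#' `three_prime_utr`, `cds`), `strand` (`+`/`-`), and optional `gene`,
#' `sigma`, `sequence` columns.
#'
#' @param path TSV path.
#' @return A tibble of regions.
#' @export
read_region_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("scaffold", "start", "end", "id", "kind", "strand") %in% names(df)))
  bad <- setdiff(unique(df$kind), region_kinds())
  if (length(bad) > 0) {
    stop("unknown region kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$start >= df$end)) stop("region with start >= end", call. = FALSE)
  for (opt in c("gene", "sigma", "sequence")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_character_
  }
  tibble::as_tibble(df)
}

#' @rdname read_region_tsv
#' @export
region_kinds <- function() {
  c("promoter", "five_prime_utr", "three_prime_utr", "cds")
}
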