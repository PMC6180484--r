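#' Fitness of a non-coding region in one condition
#'
#' The region's score is the plain average of the raw fitness of every
#' insertion whose genomic position falls inside the region's half-open
#' interval `[start, end)`.  Insertions on both strands are pooled.
#'
#' @param insertions Tibble from [read_insertion_tsv()] (columns `position`,
#'   `scaffold`, plus condition columns).
#' @param region One-row tibble (or list) with `scaffold`, `start`, `end`.
#' @param condition Condition column name.
#' @return Mean fitness, or `NA` when no insertion with a score falls in the
#'   region.
#' @export
region_fitness <- function(insertions, region, condition) {
  if (!condition %in% names(insertions)) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  inside <- insertions$scaffold == region$scaffold &
    insertions$position >= region$start & insertions$position < region$end
  x <- insertions[[condition]][inside]
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Region-by-condition fitness matrix
#'
#' Applies [region_fitness()] to every region and condition.
#'
#' @param insertions Insertion tibble (see [read_insertion_tsv()]).
#' @param regions Region tibble (see [read_region_tsv()]).
#' @param conditions Condition column names; default: every non-coordinate
#'   column of `insertions`.
#' @return A raw [profile_matrix] with region ids on the rows.
#' @export
region_fitness_matrix <- function(insertions, regions,
                                  conditions = NULL) {
  if (is.null(conditions)) {
    conditions <- setdiff(names(insertions), c("position", "scaffold"))
  }
  vals <- matrix(NA_real_, nrow(regions), length(conditions),
                 dimnames = list(regions$id, conditions))
  for (i in seq_len(nrow(regions))) {
    inside <- insertions$scaffold == regions$scaffold[i] &
      insertions$position >= regions$start[i] &
      insertions$position < regions$end[i]
    if (!any(inside)) next
    sub <- insertions[inside, conditions, drop = FALSE]
    vals[i, ] <- vapply(sub, function(x) {
      x <- x[is.finite(x)]
      if (length(x) == 0) NA_real_ else mean(x)
    }, 0)
  }
  profile_matrix(vals)
}

#' Rank promoters by fitness effect for motif export
#'
#' Orders promoter regions by their score under one condition (or a
#' condition pair difference), most negative fitness effect first by
#' default, with lexicographic promoter-id tie-breaks.  Promoters without a
#' sequence are dropped (counted in the `n_excluded` attribute).
#'
#' @param matrix A region [profile_matrix] (rows = region ids).
#' @param regions Region tibble; only rows with `kind == "promoter"` are used.
#' @param condition A condition id, or a length-2 character vector
#'   `c(cond_a, cond_b)` scored as their difference.
#' @param decreasing If `TRUE`, rank strongest positive effect first.
#' @return Tibble with `id`, `score`, `sequence`, in rank order.
#' @export
ranked_promoter_list <- function(matrix, regions, condition,
                                 decreasing = FALSE) {
  stopifnot(inherits(matrix, "profile_matrix"))
  proms <- dplyr::filter(regions, .data$kind == "promoter",
                         .data$id %in% rownames(matrix))
  score <- if (length(condition) == 2) {
    matrix[proms$id, condition[1]] - matrix[proms$id, condition[2]]
  } else {
    if (!condition %in% colnames(matrix)) {
      stop("unknown condition: ", condition, call. = FALSE)
    }
    matrix[proms$id, condition]
  }
  out <- tibble::tibble(id = proms$id, score = unname(score),
                        sequence = proms$sequence)
  n_all <- nrow(out)
  out <- dplyr::filter(out, !is.na(.data$sequence), !is.na(.data$score))
  n_excluded <- n_all - nrow(out)
  if (n_excluded > 0) {
    warning(n_excluded, " promoter(s) without sequence or score excluded",
            call. = FALSE)
  }
  out <- dplyr::arrange(out,
                        if (decreasing) -.data$score else .data$score,
                        .data$id)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write a ranked promoter list as FASTA
#'
#' @param ranked Tibble from [ranked_promoter_list()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_ranked_fasta <- function(ranked, path) {
  lines <- as.vector(rbind(
    paste0(">", ranked$id, " score=", signif(ranked$score, 6)),
    ranked$sequence
  ))
  writeLines(lines, path)
  invisible(path)
}
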