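#' Collapse gene scores to one reaction score (max-min over the GPR)
#'
#' Knocking out any subunit of a complex disables that protein, so an AND
#' clause takes the *minimum* of its genes' fitness; isozymes back each other
#' up, so the reaction takes the *maximum* over its clauses.  A clause with a
#' missing gene score is not evaluable and is dropped; if every clause drops,
#' the reaction score is missing for that condition.
#'
#' @param reaction_gpr The reaction's [gpr] rule.
#' @param gene_scores Named numeric vector, gene id -> score (`NA` allowed;
#'   absent genes count as missing).
#' @return The max-min score, or `NA` when no clause is evaluable.
#' @export
reaction_score <- function(reaction_gpr, gene_scores) {
  if (is.null(reaction_gpr)) {
    stop("reaction has no GPR (orphan); no score is defined", call. = FALSE)
  }
  stopifnot(inherits(reaction_gpr, "gpr"))
  clause_scores <- vapply(reaction_gpr, function(cl) {
    x <- gene_scores[cl]
    if (length(x) < length(cl) || anyNA(x) || !all(is.finite(x))) NA_real_
    else min(x)
  }, 0)
  if (all(is.na(clause_scores))) return(NA_real_)
  max(clause_scores, na.rm = TRUE)
}

#' Build the reaction-by-condition fitness matrix
#'
#' For every non-orphan reaction and condition, collapses the raw gene
#' matrix with [reaction_score()], then Z-normalizes the resulting reaction
#' matrix per condition over the reactions retaining at least one finite
#' value.
#'
#' @param model A [metabolic_model].
#' @param gene_matrix Raw gene [profile_matrix] (pre-normalization for
#'   fitness data).
#' @param normalize Z-normalize the collapsed matrix (default `TRUE`).
#' @return A [profile_matrix] over non-orphan reactions with data; each
#'   row carries the fraction of its GPR genes present in `gene_matrix`
#'   in the `coverage` attribute (named numeric vector).
#' @export
build_reaction_matrix <- function(model, gene_matrix, normalize = TRUE) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(gene_matrix, "profile_matrix"))
  non_orphan <- model$reactions[!is_orphan(model), ]
  if (nrow(non_orphan) == 0) stop("model has no non-orphan reaction", call. = FALSE)
  conds <- colnames(gene_matrix)
  vals <- matrix(NA_real_, nrow(non_orphan), length(conds),
                 dimnames = list(non_orphan$id, conds))
  coverage <- stats::setNames(numeric(nrow(non_orphan)), non_orphan$id)
  for (i in seq_len(nrow(non_orphan))) {
    g <- non_orphan$gpr[[i]]
    genes <- gpr_genes(g)
    have <- intersect(genes, rownames(gene_matrix))
    coverage[i] <- length(have) / length(genes)
    if (length(have) == 0) next
    sub <- gene_matrix[have, , drop = FALSE]
    for (j in seq_along(conds)) {
      vals[i, j] <- reaction_score(g, stats::setNames(sub[, j], have))
    }
  }
  keep <- rowSums(is.finite(vals)) > 0
  if (!any(keep)) stop("no evaluable reaction", call. = FALSE)
  out <- profile_matrix(vals[keep, , drop = FALSE])
  if (normalize) out <- z_normalize(out)
  attr(out, "coverage") <- coverage[keep]
  out
}

#' Reaction-level expression matrices, one per dataset
#'
#' Expression samples are Z-normalized per condition *before* the GPR
#' max-min collapse (expression scales differ between genes), then the
#' collapsed reaction matrix is Z-normalized again.  Datasets are kept
#' separate; downstream scores average across datasets rather than
#' concatenating samples.
#'
#' @param model A [metabolic_model].
#' @param expr_matrices Named list of gene [profile_matrix] objects, one per
#'   expression dataset.
#' @param covered_genes Optional character vector (e.g. genes covered by the
#'   fitness screen); expression rows outside it are dropped first.
#' @return Named list of normalized reaction [profile_matrix] objects.
#' @export
build_expression_reaction_matrix <- function(model, expr_matrices,
                                             covered_genes = NULL) {
  stopifnot(is.list(expr_matrices), length(expr_matrices) > 0)
  if (is.null(names(expr_matrices)) || any(!nzchar(names(expr_matrices)))) {
    stop("`expr_matrices` must be a named list (one name per dataset)",
         call. = FALSE)
  }
  purrr::map(expr_matrices, function(m) {
    stopifnot(inherits(m, "profile_matrix"))
    if (!is.null(covered_genes)) {
      keep <- intersect(rownames(m), covered_genes)
      if (length(keep) == 0) {
        stop("no expression gene overlaps the covered gene set", call. = FALSE)
      }
      m <- profile_matrix(m[keep, , drop = FALSE])
    }
    if (ncol(m) < 2) {
      stop("an expression dataset needs >= 2 samples to normalize",
           call. = FALSE)
    }
    build_reaction_matrix(model, z_normalize(m), normalize = TRUE)
  })
}
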