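#' Association Likelihood Score (ALS) of one candidate for one reaction
#'
#' The ALS of candidate element `candG` for an adequate reaction `Ro` is the
#' mean Spearman correlation of the candidate's profile vector with the two
#' most-correlated profile vectors among `Ro`'s profiled non-orphan
#' neighbors.  Two neighbors is the minimum that lets a single gap in a
#' linear pathway be bridged.
#'
#' @param reaction Reaction id (must be adequate in `graph`).
#' @param cand_vector Condition-named numeric vector (the candidate's
#'   Z-normalized profile).
#' @param graph A `neighborhood_graph` (see [greedy_prune()]).
#' @param reaction_matrix Normalized reaction [profile_matrix].
#' @param min_overlap Minimum shared finite conditions per correlation
#'   (default 3); neighbors below it are skipped.
#' @return The ALS, in `[-1, 1]`.
#' @export
als <- function(reaction, cand_vector, graph, reaction_matrix,
                min_overlap = 3L) {
  stopifnot(inherits(graph, "neighborhood_graph"),
            inherits(reaction_matrix, "profile_matrix"))
  if (!isTRUE(graph$adequacy[reaction])) {
    stop("reaction '", reaction, "' is not adequate for neighborhood scoring",
         call. = FALSE)
  }
  nb <- scoring_neighbors(graph, reaction, reaction_matrix)
  cand <- matrix(cand_vector, nrow = 1,
                 dimnames = list("cand", names(cand_vector)))
  rho <- cross_spearman(cand, reaction_matrix[nb, , drop = FALSE],
                        min_overlap = min_overlap)[1, ]
  rho <- rho[!is.na(rho)]
  if (length(rho) < 2) {
    stop("fewer than 2 usable neighbors for reaction '", reaction, "'",
         call. = FALSE)
  }
  mean(sort(rho, decreasing = TRUE)[1:2])
}

# neighbors usable for scoring: profiled non-orphans present in the matrix
scoring_neighbors <- function(graph, reaction, reaction_matrix) {
  nb <- neighbors_of(graph, reaction)
  intersect(intersect(nb, graph$profiled), rownames(reaction_matrix))
}

# ALS for every row of cand_matrix against every adequate reaction in
# `reactions`: mean of the top-2 correlations with each reaction's usable
# neighbors. exclude: reaction id whose vector must not serve as a neighbor
# (leave-one-out).  Returns candidates x reactions matrix.
als_matrix <- function(cand_matrix, reactions, graph, reaction_matrix,
                       min_overlap = 3L, exclude = character()) {
  C <- cross_spearman(cand_matrix, reaction_matrix, min_overlap = min_overlap)
  out <- matrix(NA_real_, nrow(cand_matrix), length(reactions),
                dimnames = list(rownames(cand_matrix), reactions))
  for (r in reactions) {
    nb <- setdiff(scoring_neighbors(graph, r, reaction_matrix), exclude)
    if (length(nb) < 2) next
    sub <- C[, nb, drop = FALSE]
    out[, r] <- apply(sub, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) NA_real_ else mean(sort(x, decreasing = TRUE)[1:2])
    })
  }
  out
}

#' Promoter-adjusted assignment score
#'
#' A candidate gene's ALS is adjusted by the ALS of its known promoters for
#' the same reaction: `ALS(Ro, candG) + alpha * sum_i ALS(Ro, candP_i)`.
#' A gene without mapped promoters keeps its unadjusted score.
#'
#' @param gene_als The candidate gene's ALS.
#' @param promoter_als Numeric vector of the gene's promoters' ALS values
#'   (may be empty; `NA` entries are dropped).
#' @param alpha Promoter weight (default 0.21).
#' @return The adjusted score.
#' @export
als_promoter_adjusted <- function(gene_als, promoter_als = numeric(),
                                  alpha = 0.21) {
  promoter_als <- promoter_als[!is.na(promoter_als)]
  if (length(promoter_als) == 0) return(gene_als)
  gene_als + alpha * sum(promoter_als)
}

#' Expression-based assignment score across datasets
#'
#' Each expression dataset yields its own neighborhood score; the combined
#' expression score is their arithmetic mean (averaging per-dataset scores
#' outperforms concatenating samples into one vector).
#'
#' @param dataset_scores Numeric vector, one ALS per expression dataset
#'   (`NA` for unusable datasets).
#' @return Mean over usable datasets, or `NA` when none is usable.
#' @export
als_expression <- function(dataset_scores) {
  x <- dataset_scores[!is.na(dataset_scores)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Combine fitness- and expression-based scores
#'
#' Equal-weight average of the two data sources.  When the expression score
#' is missing the fitness score is used alone (and vice versa); callers flag
#' such fallbacks.
#'
#' @param fit_score,expr_score Numeric scalars (`NA` allowed).
#' @return `(fit + expr)/2`, the surviving score when one is missing, or
#'   `NA` when both are.
#' @export
als_combined <- function(fit_score, expr_score) {
  if (is.na(fit_score) && is.na(expr_score)) return(NA_real_)
  if (is.na(expr_score)) return(fit_score)
  if (is.na(fit_score)) return(expr_score)
  (fit_score + expr_score) / 2
}

#' Rank candidate genes for one reaction
#'
#' @param scores Named numeric vector, candidate id -> score (`NA` scores
#'   are dropped).
#' @param top_k Number of candidates to keep (default 20); `Inf` keeps all.
#' @return Tibble with `gene_id`, `score`, `rank`; descending score, ties
#'   broken by gene id so the order is a reproducible total order.
#' @export
rank_candidates <- function(scores, top_k = 20L) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no scored candidate", call. = FALSE)
  ord <- order(-scores, names(scores))
  out <- tibble::tibble(
    gene_id = names(scores)[ord],
    score = unname(scores[ord]),
    rank = seq_along(ord)
  )
  if (is.finite(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  out
}

#' Uniform null baselines for gene-to-reaction assignment
#'
#' `weak_udist()` assumes candidates are drawn uniformly from all genes: a
#' random top-`G` list for each of `R` reactions identifies
#' `G * R / total_genes` true reaction genes in expectation.
#' `strong_udist()` assumes every pick is a true gene of *some* reaction,
#' each crediting the average number of genes per reaction: `G * avg`.
#'
#' @param G Number of top candidates considered per reaction.
#' @param R Number of reactions evaluated.
#' @param total_genes Size of the candidate gene pool.
#' @return Expected number of correctly identified reactions.
#' @export
weak_udist <- function(G, R, total_genes) {
  if (total_genes <= 0) stop("total_genes must be positive", call. = FALSE)
  G * R / total_genes
}

#' @rdname weak_udist
#' @param avg_genes_per_rxn Average number of true genes per reaction
#'   (see [mean_genes_per_reaction()]).
#' @export
strong_udist <- function(G, avg_genes_per_rxn) {
  if (avg_genes_per_rxn < 0) stop("avg_genes_per_rxn must be >= 0", call. = FALSE)
  G * avg_genes_per_rxn
}

#' Confidence of a gene-to-reaction assignment score
#'
#' Compares an observed assignment score `sigma` with empirical score
#' distributions for known (true) and spurious (false) gene-reaction pairs,
#' both estimated by leave-one-out on non-orphan reactions.  Tail
#' probabilities are inclusive empirical survival fractions
#' `P(score >= sigma)`.
#'
#' The *Bayesian* confidence is `P(>=sigma | true) * p_true / P(>=sigma)`
#' with the marginal formed from the prior mixture of the two empirical
#' tails; the *unbiased* confidence is
#' `P(>=sigma|true) / (P(>=sigma|true) + P(>=sigma|false))`.
#'
#' @param sigma Observed score(s); vectorized.
#' @param true_scores,false_scores Non-empty numeric vectors of scores for
#'   known and spurious pairs.
#' @param p_true Prior probability that a random (gene, reaction) pairing is
#'   correct (see [assignment_prior()]).
#' @return Tibble with `sigma`, `bayesian`, `unbiased`; both confidences are
#'   `NA` when `sigma` exceeds every observed score in both distributions.
#' @export
assignment_confidence <- function(sigma, true_scores, false_scores, p_true) {
  true_scores <- true_scores[!is.na(true_scores)]
  false_scores <- false_scores[!is.na(false_scores)]
  if (length(true_scores) == 0 || length(false_scores) == 0) {
    stop("both score distributions must be non-empty", call. = FALSE)
  }
  if (p_true <= 0 || p_true >= 1) stop("p_true must be in (0,1)", call. = FALSE)
  p_t <- vapply(sigma, function(s) mean(true_scores >= s), 0)
  p_f <- vapply(sigma, function(s) mean(false_scores >= s), 0)
  marginal <- p_true * p_t + (1 - p_true) * p_f
  both_zero <- p_t == 0 & p_f == 0
  bayes <- ifelse(both_zero, NA_real_, p_true * p_t / marginal)
  unbiased <- ifelse(both_zero, NA_real_, p_t / (p_t + p_f))
  tibble::tibble(sigma = sigma, bayesian = bayes, unbiased = unbiased)
}

#' Prior probability of a correct gene-reaction pairing
#'
#' Number of true (gene, reaction) pairs over the number of possible
#' (candidate gene, non-orphan reaction) pairs for a model and a candidate
#' pool.
#'
#' @param model A [metabolic_model].
#' @param candidate_genes Character vector (e.g. genes with fitness data).
#' @return A probability in (0, 1).
#' @export
assignment_prior <- function(model, candidate_genes) {
  non_orphan <- model$reactions$gpr[!is_orphan(model)]
  if (length(non_orphan) == 0 || length(candidate_genes) == 0) {
    stop("need non-orphan reactions and a candidate pool", call. = FALSE)
  }
  true_pairs <- sum(vapply(non_orphan, function(g) {
    length(intersect(gpr_genes(g), candidate_genes))
  }, 0L))
  true_pairs / (length(candidate_genes) * length(non_orphan))
}
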