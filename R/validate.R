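#' Leave-one-out validation of gene-to-reaction assignment
#'
#' Casts each adequate non-orphan reaction as an orphan in turn: the
#' reaction's own profile vector is never used as a neighbor, every gene
#' with a fitness vector (including the reaction's own genes, which are the
#' recovery targets) is scored with the neighborhood ALS, and the best rank
#' attained by a true gene is recorded.  Accuracy at `k` is the fraction of
#' validated reactions whose best true-gene rank is at most `k`.
#'
#' @param model A [metabolic_model].
#' @param gene_matrix Raw gene fitness [profile_matrix].
#' @param graph Optional pre-built `neighborhood_graph`; by default
#'   [greedy_prune()] is run with `cutoff`.
#' @param k_max Largest k of the accuracy curve (default 20).
#' @param mode `"first_gene"` asks for any true gene; `"second_gene"`
#'   restricts to reactions with >= 2 true genes, removes the best-ranked
#'   true gene and asks for another.
#' @param conditions Optional character vector of condition ids to restrict
#'   the fitness matrix to (condition-subsampling experiments).
#' @param expr_matrices Optional named list of raw gene expression
#'   [profile_matrix] objects, one per dataset; when given, scores are the
#'   fitness/expression combination of [als_combined()].
#' @param cutoff Currency-metabolite pruning cutoff (default 11).
#' @param min_overlap Minimum pairwise-complete conditions per Spearman
#'   correlation (default 3).
#' @param max_false Cap on collected spurious-pair scores for the
#'   confidence distributions (random subsample beyond it).
#' @return An `orphanfit_validation` object: per-reaction ranks, the
#'   accuracy curve, uniform baselines, and empirical true/false score
#'   distributions.
#' @seealso [assignment_confidence()], [autoplot.orphanfit_validation()]
#' @export
loo_validate <- function(model, gene_matrix, graph = NULL, k_max = 20L,
                         mode = c("first_gene", "second_gene"),
                         conditions = NULL, expr_matrices = NULL,
                         cutoff = 11L, min_overlap = 3L,
                         max_false = 50000L) {
  mode <- match.arg(mode)
  if (k_max < 1) stop("k_max must be >= 1", call. = FALSE)
  stopifnot(inherits(model, "metabolic_model"),
            inherits(gene_matrix, "profile_matrix"))
  if (!is.null(conditions)) {
    missing <- setdiff(conditions, colnames(gene_matrix))
    if (length(missing) > 0) {
      stop("unknown condition(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    gene_matrix <- profile_matrix(gene_matrix[, conditions, drop = FALSE])
  }
  reaction_matrix <- build_reaction_matrix(model, gene_matrix)
  if (is.null(graph)) {
    graph <- greedy_prune(model, profiled = rownames(reaction_matrix),
                          cutoff = cutoff)
  }
  orphan <- is_orphan(model)
  validated <- intersect(adequate_reactions(graph),
                         model$reactions$id[!orphan])
  if (length(validated) == 0) {
    stop("no adequate non-orphan reaction to validate", call. = FALSE)
  }
  gene_z <- z_normalize(gene_matrix)
  fit_scores <- als_matrix(gene_z, validated, graph, reaction_matrix,
                           min_overlap = min_overlap)
  scores <- fit_scores
  if (!is.null(expr_matrices)) {
    expr_scores <- expression_score_matrix(model, expr_matrices, validated,
                                           graph, min_overlap,
                                           covered_genes = rownames(gene_matrix))
    scores <- combine_score_matrices(fit_scores, expr_scores)
  }

  gpr_by_id <- stats::setNames(model$reactions$gpr, model$reactions$id)
  candidates <- rownames(gene_matrix)
  rows <- purrr::map(validated, function(r) {
    truth <- intersect(gpr_genes(gpr_by_id[[r]]), candidates)
    if (mode == "second_gene" && length(truth) < 2) return(NULL)
    s <- scores[, r]
    s <- s[!is.na(s)]
    if (length(s) == 0) {
      return(tibble::tibble(reaction_id = r, n_true_genes = length(truth),
                            best_rank = NA_integer_, best_gene = NA_character_,
                            n_candidates = 0L))
    }
    ranking <- rank_candidates(s, top_k = Inf)
    hit <- dplyr::filter(ranking, .data$gene_id %in% truth)
    if (mode == "second_gene") {
      if (nrow(hit) > 0) {
        first <- hit$gene_id[1]
        ranking <- rank_candidates(s[setdiff(names(s), first)], top_k = Inf)
        hit <- dplyr::filter(ranking, .data$gene_id %in% setdiff(truth, first))
      }
    }
    tibble::tibble(
      reaction_id = r,
      n_true_genes = length(truth),
      best_rank = if (nrow(hit) > 0) hit$rank[1] else NA_integer_,
      best_gene = if (nrow(hit) > 0) hit$gene_id[1] else NA_character_,
      n_candidates = nrow(ranking)
    )
  })
  ranks <- dplyr::bind_rows(rows)
  if (nrow(ranks) == 0) {
    stop("no reaction eligible for mode '", mode, "'", call. = FALSE)
  }

  hit_at <- function(k) sum(!is.na(ranks$best_rank) & ranks$best_rank <= k)
  curve <- tibble::tibble(
    k = seq_len(k_max),
    n_hit = vapply(seq_len(k_max), hit_at, 0L),
    accuracy = vapply(seq_len(k_max), hit_at, 0L) / nrow(ranks)
  )
  baselines <- tibble::tibble(
    k = seq_len(k_max),
    weak = weak_udist(seq_len(k_max), nrow(ranks), length(candidates)),
    strong = strong_udist(seq_len(k_max), mean_genes_per_reaction(model))
  )

  # empirical score distributions for assignment confidence
  is_true <- matrix(FALSE, nrow(scores), length(validated),
                    dimnames = list(rownames(scores), validated))
  for (r in validated) {
    truth <- intersect(gpr_genes(gpr_by_id[[r]]), candidates)
    is_true[truth, r] <- TRUE
  }
  sub <- scores[, validated, drop = FALSE]
  true_scores <- sub[is_true & !is.na(sub)]
  false_scores <- sub[!is_true & !is.na(sub)]
  if (length(false_scores) > max_false) {
    false_scores <- sample(false_scores, max_false)
  }

  structure(
    list(ranks = ranks, curve = curve, baselines = baselines,
         mode = mode, k_max = k_max,
         n_conditions = ncol(gene_matrix),
         n_candidates = length(candidates),
         score_dist = list(true = true_scores, false = false_scores)),
    class = "orphanfit_validation"
  )
}

expression_score_matrix <- function(model, expr_matrices, reactions, graph,
                                    min_overlap, covered_genes) {
  rxn_expr <- build_expression_reaction_matrix(model, expr_matrices,
                                               covered_genes = covered_genes)
  per_dataset <- purrr::map(names(expr_matrices), function(ds) {
    m <- expr_matrices[[ds]]
    keep <- intersect(rownames(m), covered_genes)
    gene_z <- z_normalize(profile_matrix(m[keep, , drop = FALSE]))
    als_matrix(gene_z, reactions, graph, rxn_expr[[ds]],
               min_overlap = min_overlap)
  })
  # align on the union of genes, then average across datasets
  genes <- sort(unique(unlist(lapply(per_dataset, rownames))))
  stack <- array(NA_real_, c(length(genes), length(reactions),
                             length(per_dataset)),
                 dimnames = list(genes, reactions, NULL))
  for (d in seq_along(per_dataset)) {
    stack[rownames(per_dataset[[d]]), , d] <- per_dataset[[d]]
  }
  apply(stack, c(1, 2), function(x) als_expression(x))
}

combine_score_matrices <- function(fit_scores, expr_scores) {
  genes <- sort(union(rownames(fit_scores), rownames(expr_scores)))
  rxns <- colnames(fit_scores)
  out <- matrix(NA_real_, length(genes), length(rxns),
                dimnames = list(genes, rxns))
  for (g in genes) {
    f <- if (g %in% rownames(fit_scores)) fit_scores[g, ] else
      stats::setNames(rep(NA_real_, length(rxns)), rxns)
    e <- if (g %in% rownames(expr_scores)) expr_scores[g, rxns] else
      stats::setNames(rep(NA_real_, length(rxns)), rxns)
    out[g, ] <- mapply(als_combined, f, e)
  }
  out
}

#' @export
print.orphanfit_validation <- function(x, ...) {
  cat("<orphanfit_validation> ", nrow(x$ranks), " reactions (mode ",
      x$mode, ", ", x$n_conditions, " conditions)\n", sep = "")
  cat("  top-1 accuracy:  ", signif(x$curve$accuracy[1], 3), "\n", sep = "")
  cat("  top-", x$k_max, " accuracy: ",
      signif(x$curve$accuracy[x$k_max], 3), "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize a leave-one-out validation
#'
#' `tidy()` returns the accuracy curve with the uniform baselines
#' (expressed as expected accuracy); `glance()` returns a one-row summary.
#'
#' @param x An `orphanfit_validation` object.
#' @param ... Unused.
#' @export
tidy.orphanfit_validation <- function(x, ...) {
  dplyr::left_join(x$curve, x$baselines, by = "k") |>
    dplyr::mutate(
      weak_accuracy = .data$weak / nrow(x$ranks),
      strong_accuracy = pmin(1, .data$strong / nrow(x$ranks))
    )
}

#' @rdname tidy.orphanfit_validation
#' @export
glance.orphanfit_validation <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$ranks),
    n_candidates = x$n_candidates,
    n_conditions = x$n_conditions,
    mode = x$mode,
    top1_accuracy = x$curve$accuracy[1],
    topk_accuracy = x$curve$accuracy[x$k_max],
    k_max = x$k_max,
    median_best_rank = stats::median(x$ranks$best_rank, na.rm = TRUE)
  )
}

#' Plot a leave-one-out accuracy curve
#'
#' Accuracy (fraction of validated reactions whose true gene is in the top
#' k) against k, with the weak uniform baseline for reference.
#'
#' @param object An `orphanfit_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orphanfit_validation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$accuracy, colour = "ALS")) +
    ggplot2::geom_point(ggplot2::aes(y = .data$accuracy, colour = "ALS")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$weak_accuracy,
                                    colour = "weak uniform"),
                       linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("ALS" = "#2c7fb8",
                                            "weak uniform" = "grey40"),
                                 name = NULL) +
    ggplot2::labs(x = "k (top candidates considered)",
                  y = "fraction of reactions with a true gene in top k") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
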