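#' Assign candidate genes to adequate orphan reactions
#'
#' The end-to-end assignment pipeline: build the reaction fitness matrix
#' (GPR max-min collapse, per-condition Z-normalization), prune currency
#' metabolites, and for every adequate orphan reaction score all candidate
#' genes with the neighborhood ALS — optionally promoter-adjusted and
#' combined with expression-based scores — then rank and attach empirical
#' confidences.
#'
#' @param model A [metabolic_model].
#' @param gene_matrix Raw gene fitness [profile_matrix]; its rownames are
#'   the candidate pool.
#' @param expr_matrices Optional named list of raw expression matrices, one
#'   per dataset.
#' @param promoter_matrix Optional raw promoter fitness [profile_matrix]
#'   (rows = promoter ids), built with [region_fitness_matrix()].
#' @param promoter_map Optional tibble with `gene`, `promoter` columns
#'   linking genes to their promoters.
#' @param alpha Promoter adjustment weight (default 0.21).
#' @param cutoff Currency pruning cutoff (default 11).
#' @param top_k Candidates reported per reaction (default 20).
#' @param min_overlap Minimum shared conditions per correlation (default 3).
#' @param confidence Attach Bayesian/unbiased confidences estimated by
#'   leave-one-out on the non-orphan reactions (default `TRUE`).
#' @param p_true Prior probability of a correct pairing; default
#'   [assignment_prior()] on the model and candidate pool.
#' @param validation Optional pre-computed `orphanfit_validation` supplying
#'   the confidence score distributions (avoids re-running leave-one-out).
#' @return An `orphanfit_assignment` tibble: one row per (orphan reaction,
#'   candidate, rank <= top_k) with score components and confidences, plus
#'   attributes `adequate_orphans`, `inadequate_orphans` and `graph`.
#' @export
run_assign <- function(model, gene_matrix, expr_matrices = NULL,
                       promoter_matrix = NULL, promoter_map = NULL,
                       alpha = 0.21, cutoff = 11L, top_k = 20L,
                       min_overlap = 3L, confidence = TRUE, p_true = NULL,
                       validation = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(gene_matrix, "profile_matrix"))
  reaction_matrix <- build_reaction_matrix(model, gene_matrix)
  graph <- greedy_prune(model, profiled = rownames(reaction_matrix),
                        cutoff = cutoff)
  orphans <- orphan_reactions(model)
  targets <- intersect(adequate_reactions(graph), orphans)
  if (length(targets) == 0) {
    stop("no adequate orphan reaction in the model", call. = FALSE)
  }
  gene_z <- z_normalize(gene_matrix)
  fit_scores <- als_matrix(gene_z, targets, graph, reaction_matrix,
                           min_overlap = min_overlap)

  promoter_term <- matrix(0, nrow(fit_scores), ncol(fit_scores),
                          dimnames = dimnames(fit_scores))
  if (!is.null(promoter_matrix) && !is.null(promoter_map) && alpha != 0) {
    prom_z <- z_normalize(promoter_matrix)
    prom_scores <- als_matrix(prom_z, targets, graph, reaction_matrix,
                              min_overlap = min_overlap)
    for (g in intersect(rownames(fit_scores), promoter_map$gene)) {
      proms <- intersect(promoter_map$promoter[promoter_map$gene == g],
                         rownames(prom_scores))
      if (length(proms) == 0) next
      ps <- prom_scores[proms, , drop = FALSE]
      promoter_term[g, ] <- colSums(ps, na.rm = TRUE)
    }
  }
  adjusted <- fit_scores + alpha * promoter_term

  expr_scores <- NULL
  scores <- adjusted
  if (!is.null(expr_matrices)) {
    expr_scores <- expression_score_matrix(model, expr_matrices, targets,
                                           graph, min_overlap,
                                           covered_genes = rownames(gene_matrix))
    scores <- combine_score_matrices(adjusted, expr_scores)
  }

  dist <- NULL
  prior <- p_true
  if (confidence) {
    if (is.null(validation)) {
      validation <- loo_validate(model, gene_matrix, graph = graph,
                                 expr_matrices = expr_matrices,
                                 min_overlap = min_overlap, cutoff = cutoff)
    }
    dist <- validation$score_dist
    if (is.null(prior)) prior <- assignment_prior(model, rownames(gene_matrix))
  }

  results <- purrr::map_dfr(targets, function(r) {
    s <- scores[, r]
    s <- s[!is.na(s)]
    if (length(s) == 0) return(NULL)
    ranked <- rank_candidates(s, top_k = top_k)
    out <- dplyr::mutate(
      ranked,
      reaction_id = r,
      als_fitness = unname(fit_scores[.data$gene_id, r]),
      promoter_term = unname(promoter_term[.data$gene_id, r]),
      als_expression = if (is.null(expr_scores)) NA_real_ else {
        unname(ifelse(.data$gene_id %in% rownames(expr_scores),
                      expr_scores[.data$gene_id, r], NA_real_))
      },
      expr_fallback = !is.null(expr_scores) & is.na(.data$als_expression),
      .before = 1
    )
    dplyr::rename(out, combined = "score")
  })
  if (confidence && nrow(results) > 0) {
    conf <- assignment_confidence(results$combined, dist$true, dist$false,
                                  prior)
    results$bayesian_conf <- conf$bayesian
    results$unbiased_conf <- conf$unbiased
  }
  results <- results[, c("reaction_id", "gene_id", "rank", "als_fitness",
                         "promoter_term", "als_expression", "combined",
                         intersect(c("bayesian_conf", "unbiased_conf"),
                                   names(results)), "expr_fallback")]
  structure(results,
            class = c("orphanfit_assignment", class(results)),
            adequate_orphans = targets,
            inadequate_orphans = setdiff(orphans, targets),
            graph = graph)
}

#' @export
glance.orphanfit_assignment <- function(x, ...) {
  tibble::tibble(
    n_orphans_adequate = length(attr(x, "adequate_orphans")),
    n_orphans_inadequate = length(attr(x, "inadequate_orphans")),
    n_rows = nrow(x),
    top_score = max(x$combined)
  )
}

#' Leave-one-out validation with optional condition subsampling
#'
#' Convenience wrapper over [loo_validate()] that can repeat the validation
#' on random subsets of conditions of several sizes, the experiment that
#' shows how prediction accuracy depends on the number of measured
#' conditions.
#'
#' @param model,gene_matrix,k_max,mode,expr_matrices,cutoff,min_overlap
#'   Passed to [loo_validate()].
#' @param n_conditions Optional integer vector of condition-subset sizes.
#' @param n_seeds Random subsets drawn per size (default 10).
#' @param seed Base seed for subset draws (default 1).
#' @return When `n_conditions` is `NULL`, an `orphanfit_validation`.
#'   Otherwise a tibble with one row per (subset size, replicate):
#'   `n_conditions`, `replicate`, `top1_accuracy`, `topk_accuracy`.
#' @export
run_validate <- function(model, gene_matrix, k_max = 20L,
                         mode = "first_gene", expr_matrices = NULL,
                         cutoff = 11L, min_overlap = 3L,
                         n_conditions = NULL, n_seeds = 10L, seed = 1L) {
  if (is.null(n_conditions)) {
    return(loo_validate(model, gene_matrix, k_max = k_max, mode = mode,
                        expr_matrices = expr_matrices, cutoff = cutoff,
                        min_overlap = min_overlap))
  }
  all_conds <- colnames(gene_matrix)
  purrr::map_dfr(n_conditions, function(nc) {
    if (nc > length(all_conds)) stop("subset larger than condition count",
                                     call. = FALSE)
    purrr::map_dfr(seq_len(n_seeds), function(rep) {
      conds <- with_seed(seed + 97L * rep + nc, sample(all_conds, nc))
      v <- loo_validate(model, gene_matrix, k_max = k_max, mode = mode,
                        conditions = conds, expr_matrices = expr_matrices,
                        cutoff = cutoff, min_overlap = min_overlap)
      tibble::tibble(n_conditions = nc, replicate = rep,
                     top1_accuracy = v$curve$accuracy[1],
                     topk_accuracy = v$curve$accuracy[k_max])
    })
  })
}

#' Write a results table with a provenance header
#'
#' The header records the package version, a hash of the configuration and
#' the seed, so an output file identifies the run that produced it.
#'
#' @param results A data frame (e.g. from [run_assign()]).
#' @param path Output TSV path.
#' @param config List of run parameters (hashed into the header).
#' @param seed The run's seed.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path, config = list(), seed = NA) {
  header <- c(
    paste0("# orphanfit ", as.character(utils::packageVersion("orphanfit"))),
    paste0("# config_hash ", rlang::hash(config)),
    paste0("# seed ", seed)
  )
  writeLines(header, path)
  readr::write_tsv(as.data.frame(results), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Write a validation report as JSON
#'
#' @param validation An `orphanfit_validation` object.
#' @param path Output JSON path.
#' @param config,seed Provenance fields.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(validation, path, config = list(),
                                  seed = NA) {
  jsonlite::write_json(list(
    package = paste0("orphanfit ",
                     as.character(utils::packageVersion("orphanfit"))),
    config_hash = rlang::hash(config),
    seed = seed,
    summary = glance(validation),
    curve = tidy(validation),
    ranks = validation$ranks
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
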