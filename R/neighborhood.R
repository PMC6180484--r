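#' Reaction neighborhood graphs
#'
#' Two reactions are *neighbors* when their stoichiometries share at least
#' one retained species.  Currency metabolites (water, protons, cofactors)
#' connect almost everything and are pruned by [greedy_prune()] before the
#' neighborhood is used for gene assignment.
#'
#' @param model A [metabolic_model].
#' @param retained Character vector of species ids kept for edge
#'   computation; defaults to all model species.
#' @param profiled Character vector of reaction ids that possess a profile
#'   vector (typically `rownames(build_reaction_matrix(...))`); used for the
#'   adequacy flags.  Defaults to all non-orphan reactions.
#' @return A `neighborhood_graph`: nodes, adjacency list, shared-species
#'   count matrix, `removed_species`, and per-reaction `adequacy` flags.
#' @export
build_adjacency <- function(model, retained = NULL, profiled = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.null(retained)) retained <- model$species$id
  bad <- setdiff(retained, model$species$id)
  if (length(bad) > 0) {
    stop("retained species not in model: ", paste(utils::head(bad, 5),
                                                  collapse = ", "), call. = FALSE)
  }
  ids <- model$reactions$id
  n <- length(ids)
  shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (sp in retained) {
    members <- which(vapply(model$reactions$stoich, function(s) {
      sp %in% names(s) && s[[sp]] != 0
    }, TRUE))
    if (length(members) >= 2) {
      shared[members, members] <- shared[members, members] + 1L
    }
  }
  diag(shared) <- 0L
  new_neighborhood_graph(model, shared,
                         removed_species = setdiff(model$species$id, retained),
                         profiled = profiled)
}

new_neighborhood_graph <- function(model, shared, removed_species, profiled) {
  ids <- rownames(shared)
  orphans <- orphan_reactions(model)
  if (is.null(profiled)) profiled <- setdiff(ids, orphans)
  profiled_nonorphan <- setdiff(intersect(profiled, ids), orphans)
  g <- structure(
    list(nodes = ids, shared = shared,
         removed_species = removed_species,
         orphans = orphans, profiled = profiled_nonorphan),
    class = "neighborhood_graph"
  )
  g$adequacy <- profiled_neighbor_counts(g) >= 2L
  g
}

# per reaction: number of neighbors that are non-orphan and profiled
profiled_neighbor_counts <- function(graph) {
  adj <- graph$shared > 0L
  cols <- intersect(graph$profiled, graph$nodes)
  counts <- rowSums(adj[, cols, drop = FALSE])
  stats::setNames(as.integer(counts), graph$nodes)
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat("<neighborhood_graph> ", length(x$nodes), " reactions, ",
      sum(x$shared > 0) / 2, " edges, ",
      length(x$removed_species), " species removed, ",
      sum(x$adequacy), " adequate\n", sep = "")
  invisible(x)
}

#' Neighbors of a reaction
#' @param graph A `neighborhood_graph`.
#' @param reaction Reaction id.
#' @return Character vector of neighboring reaction ids.
#' @export
neighbors_of <- function(graph, reaction) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  if (!reaction %in% graph$nodes) stop("unknown reaction: ", reaction, call. = FALSE)
  names(which(graph$shared[reaction, ] > 0L))
}

#' Tidy a neighborhood graph into its edge list
#' @param x A `neighborhood_graph`.
#' @param ... Unused.
#' @return Tibble with `from`, `to` (from < to) and `n_shared` species.
#' @export
tidy.neighborhood_graph <- function(x, ...) {
  idx <- which(upper.tri(x$shared) & x$shared > 0L, arr.ind = TRUE)
  tibble::tibble(
    from = x$nodes[idx[, 1]],
    to = x$nodes[idx[, 2]],
    n_shared = x$shared[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' Convert to an igraph object
#' @param graph A `neighborhood_graph`.
#' @return An undirected [igraph::igraph] graph with an `orphan` vertex
#'   attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  edges <- tidy(graph)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = graph$nodes,
                          orphan = graph$nodes %in% graph$orphans)
  )
  g
}

#' Greedily prune high-frequency (currency) metabolites
#'
#' Species whose reference frequency exceeds `cutoff` are candidates for
#' removal, visited from the highest frequency down (ties broken by species
#' id).  A candidate is removed globally unless that removal would leave any
#' reaction that currently has at least two profiled non-orphan neighbors
#' with fewer than two — the minimum needed to bridge a gap in a linear
#' pathway — in which case the removal is reverted and the species kept.
#' Frequencies are computed once on the unpruned model.
#'
#' @param model A [metabolic_model].
#' @param profiled Reaction ids with profile vectors (see [build_adjacency()]).
#' @param cutoff Frequency above which a species is a pruning candidate
#'   (default 11).
#' @return A `neighborhood_graph` with `removed_species` in removal order.
#' @export
greedy_prune <- function(model, profiled = NULL, cutoff = 11L) {
  stopifnot(inherits(model, "metabolic_model"))
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  graph <- build_adjacency(model, profiled = profiled)
  freq <- metabolite_frequencies(model)
  cand <- names(freq)[freq > cutoff]
  cand <- cand[order(-freq[cand], cand)]

  ids <- graph$nodes
  index <- stats::setNames(seq_along(ids), ids)
  members_of <- lapply(model$reactions$stoich, function(s) {
    unname(index[names(s)[s != 0]])
  })
  species_members <- lapply(cand, function(sp) {
    which(vapply(model$reactions$stoich, function(s) {
      sp %in% names(s) && s[[sp]] != 0
    }, TRUE))
  })
  names(species_members) <- cand

  shared <- graph$shared
  profiled_idx <- index[graph$profiled]
  np_count <- profiled_neighbor_counts(graph)
  removed <- character()

  for (sp in cand) {
    members <- species_members[[sp]]
    if (length(members) < 2) {
      removed <- c(removed, sp)  # no edge depends on it
      next
    }
    pairs <- utils::combn(members, 2)
    # edges that disappear if sp is removed
    lost <- pairs[, shared[t(pairs)] == 1L, drop = FALSE]
    if (ncol(lost) == 0) {
      shared[t(pairs)] <- shared[t(pairs)] - 1L
      shared[t(pairs[2:1, , drop = FALSE])] <-
        shared[t(pairs[2:1, , drop = FALSE])] - 1L
      removed <- c(removed, sp)
      next
    }
    delta <- stats::setNames(integer(0), character(0))
    bump <- function(i, by) {
      key <- as.character(i)
      delta[key] <<- (delta[key] %|NA0|% 0L) + by
    }
    for (e in seq_len(ncol(lost))) {
      i <- lost[1, e]; j <- lost[2, e]
      if (j %in% profiled_idx) bump(i, 1L)
      if (i %in% profiled_idx) bump(j, 1L)
    }
    affected <- as.integer(names(delta))
    before <- np_count[affected]
    after <- before - unname(delta)
    if (any(before >= 2L & after < 2L)) next  # revert: keep the species
    # commit
    shared[t(pairs)] <- shared[t(pairs)] - 1L
    shared[t(pairs[2:1, , drop = FALSE])] <-
      shared[t(pairs[2:1, , drop = FALSE])] - 1L
    np_count[affected] <- after
    removed <- c(removed, sp)
  }

  out <- new_neighborhood_graph(model, shared, removed_species = removed,
                                profiled = graph$profiled)
  out
}

`%|NA0|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Reactions adequate for neighborhood-based scoring
#'
#' A reaction (orphan or not) is *adequate* when it has at least two
#' non-orphan neighbors possessing profile vectors, so a candidate gene can
#' be correlated against two independent neighbors.
#'
#' @param graph A `neighborhood_graph`.
#' @return Character vector of adequate reaction ids.
#' @export
adequate_reactions <- function(graph) {
  stopifnot(inherits(graph, "neighborhood_graph"))
  names(which(graph$adequacy))
}
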