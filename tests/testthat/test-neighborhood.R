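test_that("adjacency edges require a shared retained species", {
  m <- tiny_model()  # R1-B-R2, R2-C-R3; R4 detached
  g <- build_adjacency(m)
  expect_setequal(neighbors_of(g, "R2"), c("R1", "R3"))
  expect_equal(neighbors_of(g, "R4"), character())
  # dropping the shared species removes the edge
  g2 <- build_adjacency(m, retained = setdiff(m$species$id, "B"))
  expect_equal(neighbors_of(g2, "R1"), character())
  expect_error(build_adjacency(m, retained = "nope"), "not in model")
})

test_that("adjacency matches a pairwise stoichiometry-intersection oracle", {
  set.seed(31)
  rx <- tibble::tibble(
    id = sprintf("R%02d", 1:15),
    stoich = lapply(1:15, function(i) {
      sp <- sample(LETTERS[1:10], sample(2:4, 1))
      stats::setNames(rep(1, length(sp)), sp)
    }),
    gpr = rep(list(NULL), 15)
  )
  m <- metabolic_model(rx)
  g <- build_adjacency(m)
  edges <- tidy(g)
  for (i in 1:14) {
    for (j in (i + 1):15) {
      shared <- length(intersect(names(rx$stoich[[i]]), names(rx$stoich[[j]])))
      present <- any(edges$from == rx$id[i] & edges$to == rx$id[j])
      expect_equal(present, shared > 0)
      if (present) {
        expect_equal(edges$n_shared[edges$from == rx$id[i] &
                                      edges$to == rx$id[j]], shared)
      }
    }
  }
})

# chain of 4 single-gene reactions plus one currency metabolite in all of
# them; removing the currency would leave the chain ends with 1 neighbor
revert_trap_model <- function() {
  metabolic_model(tibble::tibble(
    id = c("R1", "R2", "R3", "R4"),
    stoich = list(
      c(s1 = -1, s2 = 1, cur = -1),
      c(s2 = -1, s3 = 1, cur = -1),
      c(s3 = -1, s4 = 1, cur = -1),
      c(s4 = -1, s5 = 1, cur = -1)
    ),
    gpr = lapply(sprintf("g%d", 1:4), parse_gpr)
  ))
}

test_that("greedy_prune removes harmless currency species and reverts traps", {
  # trap: cur connects R1-R3, R1-R4, R2-R4; with cur every reaction has >=2
  # profiled neighbors, without it R1 and R4 drop to 1 -> must be kept
  m <- revert_trap_model()
  g <- greedy_prune(m, cutoff = 2L)
  expect_equal(g$removed_species, character())
  expect_setequal(neighbors_of(g, "R1"), c("R2", "R3", "R4"))

  # harmless: same chain but ends tied together by an extra species, so the
  # currency removal keeps everyone at >= 2 neighbors
  m2 <- metabolic_model(tibble::tibble(
    id = c("R1", "R2", "R3", "R4"),
    stoich = list(
      c(s1 = -1, s2 = 1, loop = 1, cur = -1),
      c(s2 = -1, s3 = 1, cur = -1),
      c(s3 = -1, s4 = 1, cur = -1),
      c(s4 = -1, loop = -1, cur = -1)
    ),
    gpr = lapply(sprintf("g%d", 1:4), parse_gpr)
  ))
  g2 <- greedy_prune(m2, cutoff = 2L)
  expect_equal(g2$removed_species, "cur")
  expect_setequal(neighbors_of(g2, "R1"), c("R2", "R4"))
  expect_error(greedy_prune(m2, cutoff = -1), "cutoff")
})

test_that("species at the cutoff are never candidates; no-op without candidates", {
  m <- tiny_model()
  g <- greedy_prune(m, cutoff = 1L)  # B and C have frequency 2 > 1
  # removing B would leave R1 with 0 neighbors, but R1 had only 1 before, so
  # the removal is allowed (only reactions at >=2 block removals)
  expect_true("B" %in% g$removed_species)
  g2 <- greedy_prune(m, cutoff = 2L)  # nothing above cutoff
  expect_equal(g2$removed_species, character())
  expect_equal(g2$shared, build_adjacency(m)$shared)
})

test_that("pruning is deterministic, ordered by frequency then id, and only removes edges", {
  spec <- fixture_spec(seed = 5)
  tm <- make_toy_model(spec)
  g1 <- greedy_prune(tm$model)
  g2 <- greedy_prune(tm$model)
  expect_identical(g1$removed_species, g2$removed_species)
  expect_equal(g1$removed_species, sort(tm$truth$currency))
  before <- build_adjacency(tm$model)
  expect_true(all(g1$shared <= before$shared))
  # revert guarantee: every reaction adequate before pruning with >= 2
  # profiled neighbors still has >= 2 afterwards
  counts_before <- rowSums(before$shared[, before$profiled] > 0)
  counts_after <- rowSums(g1$shared[, g1$profiled] > 0)
  expect_true(all(counts_after[counts_before >= 2] >= 2))
})

test_that("adequacy needs two profiled non-orphan neighbors", {
  m <- star_model(3)
  # all three neighbors profiled -> orphan adequate
  g <- build_adjacency(m, profiled = c("N1", "N2", "N3"))
  expect_true("RO" %in% adequate_reactions(g))
  # exactly two -> boundary, still adequate
  g2 <- build_adjacency(m, profiled = c("N1", "N2"))
  expect_true("RO" %in% adequate_reactions(g2))
  # one -> inadequate
  g3 <- build_adjacency(m, profiled = "N1")
  expect_false("RO" %in% adequate_reactions(g3))
  # planted adequacy in the synthetic fixture matches the computed set
  spec <- fixture_spec(seed = 8)
  tm <- make_toy_model(spec)
  fit <- simulate_fitness(tm$model, tm$truth, spec)
  rxn <- build_reaction_matrix(tm$model, fit$gene_matrix)
  gp <- greedy_prune(tm$model, profiled = rownames(rxn))
  expect_setequal(adequate_reactions(gp), tm$truth$adequate)
})

test_that("graph exports to igraph with orphan annotations", {
  m <- tiny_model()
  ig <- as_igraph(build_adjacency(m))
  expect_equal(igraph::vcount(ig), 4)
  expect_equal(igraph::ecount(ig), 2)
  expect_equal(sum(igraph::V(ig)$orphan), 1)
})
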