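test_that("ALS is the mean of the two best neighbor correlations", {
  m <- star_model(3)
  g <- build_adjacency(m, profiled = c("N1", "N2", "N3"))
  rxn <- pm(matrix(c(1, 2, 3, 4,
                     4, 3, 2, 1,
                     2, 1, 4, 3), 3, 4, byrow = TRUE,
                   dimnames = list(c("N1", "N2", "N3"), paste0("c", 1:4))))
  cand <- stats::setNames(c(1, 2, 3, 4), paste0("c", 1:4))
  # rho = 1, -1, 0.6 -> mean of top two = 0.8
  expect_equal(als("RO", cand, g, rxn), 0.8)
  # exactly two perfectly correlated neighbors -> 1
  g2 <- build_adjacency(m, profiled = c("N1", "N3"))
  rxn2 <- pm(matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, 4, byrow = TRUE,
                    dimnames = list(c("N1", "N3"), paste0("c", 1:4))))
  expect_equal(als("RO", cand, g2, rxn2), 1)
  # inadequate reaction errors
  g3 <- build_adjacency(m, profiled = "N1")
  expect_error(als("RO", cand, g3, rxn), "not adequate")
})

test_that("top-2 of single correlations equals the best neighbor pair mean", {
  set.seed(41)
  m <- star_model(5)
  g <- build_adjacency(m, profiled = paste0("N", 1:5))
  for (i in 1:20) {
    rxn <- pm(matrix(rnorm(5 * 8), 5, 8,
                     dimnames = list(paste0("N", 1:5), paste0("c", 1:8))))
    cand <- stats::setNames(rnorm(8), paste0("c", 1:8))
    rho <- vapply(1:5, function(j) {
      cor(cand, rxn[j, ], method = "spearman")
    }, 0)
    pair_means <- combn(5, 2, function(p) mean(rho[p]))
    expect_equal(als("RO", cand, g, rxn), max(pair_means))
  }
})

test_that("ALS is rank-based and bounded", {
  set.seed(43)
  m <- star_model(3)
  g <- build_adjacency(m, profiled = paste0("N", 1:3))
  rxn <- pm(matrix(rnorm(24), 3, 8,
                   dimnames = list(paste0("N", 1:3), paste0("c", 1:8))))
  cand <- stats::setNames(rnorm(8), paste0("c", 1:8))
  base <- als("RO", cand, g, rxn)
  expect_gte(base, -1); expect_lte(base, 1)
  # invariant under monotone transforms of the candidate vector
  expect_equal(als("RO", exp(2 * cand) + 5, g, rxn), base)
})

test_that("promoter adjustment follows the alpha-weighted sum", {
  expect_equal(als_promoter_adjusted(0.5, 0.4, alpha = 0.21), 0.584)
  expect_equal(als_promoter_adjusted(0.5, numeric()), 0.5)
  expect_equal(als_promoter_adjusted(0.5, c(0.4, -0.2), alpha = 0.21), 0.542)
})

test_that("expression scores average across datasets; combination averages sources", {
  expect_equal(als_expression(c(0.3, 0.5)), 0.4)
  expect_equal(als_expression(0.7), 0.7)
  expect_equal(als_expression(c(0.3, NA)), 0.3)
  expect_true(is.na(als_expression(c(NA_real_, NA_real_))))
  expect_equal(als_combined(0.8, 0.4), 0.6)
  expect_equal(als_combined(0.3, 0.3), 0.3)
  expect_equal(als_combined(0.8, NA), 0.8)  # fitness-only fallback
  expect_true(is.na(als_combined(NA, NA)))
})

test_that("candidate ranking is a reproducible total order", {
  scores <- c(gB = 0.9, gC = 0.1, gA = 0.9)
  out <- rank_candidates(scores)
  expect_equal(out$gene_id, c("gA", "gB", "gC"))
  expect_equal(out$rank, 1:3)
  expect_equal(rank_candidates(scores, top_k = 1)$gene_id, "gA")
  expect_error(rank_candidates(c(a = NA_real_)), "no scored")
  set.seed(47)
  s <- stats::setNames(rnorm(50), sprintf("g%02d", 1:50))
  expect_identical(rank_candidates(s), rank_candidates(s[sample(50)]))
})

test_that("uniform baselines reproduce closed forms and scale linearly", {
  expect_equal(weak_udist(10, 1556, 3646), 10 * 1556 / 3646)
  expect_equal(weak_udist(0, 100, 500), 0)
  expect_equal(weak_udist(500, 1, 500), 1)
  expect_equal(strong_udist(10, 3.126), 31.26)
  expect_equal(strong_udist(0, 2), 0)
  expect_error(weak_udist(10, 5, 0), "positive")
  for (G in c(1, 7, 19)) {
    expect_equal(weak_udist(3 * G, 10, 100), 3 * weak_udist(G, 10, 100))
    expect_equal(strong_udist(3 * G, 1.5), 3 * strong_udist(G, 1.5))
  }
})

test_that("assignment confidences follow the empirical tail definitions", {
  true_s <- c(rep(1, 500), rep(0, 500))    # P(>=0.5 | true) = 0.5
  false_s <- c(1, rep(0, 999))             # P(>=0.5 | false) = 0.001
  out <- assignment_confidence(0.5, true_s, false_s, p_true = 0.00044)
  expect_equal(out$unbiased, 0.5 / (0.5 + 0.001))
  marginal <- 0.00044 * 0.5 + (1 - 0.00044) * 0.001
  expect_equal(out$bayesian, 0.00044 * 0.5 / marginal)
  # symmetric tails -> unbiased 0.5; perfect separation -> 1
  sym <- assignment_confidence(0.5, c(0, 1), c(0, 1), p_true = 0.1)
  expect_equal(sym$unbiased, 0.5)
  sep <- assignment_confidence(0.5, c(0.9, 0.8), c(0.1, 0.2), p_true = 0.1)
  expect_equal(sep$unbiased, 1)
  # sigma above every observed score -> flagged missing
  high <- assignment_confidence(2, c(0, 1), c(0, 1), p_true = 0.1)
  expect_true(is.na(high$bayesian) && is.na(high$unbiased))
  # monotone in the true tail with the false tail held fixed
  false_fixed <- c(rep(0, 8), rep(1, 2))        # P(>=0.5 | false) = 0.2
  tails <- seq(0.1, 0.9, by = 0.2)
  ub <- vapply(tails, function(pt) {
    true_d <- c(rep(1, round(pt * 100)), rep(0, 100 - round(pt * 100)))
    assignment_confidence(0.5, true_d, false_fixed, 0.1)$unbiased
  }, 0)
  expect_true(all(diff(ub) > 0))
})

test_that("the assignment prior counts true pairs over possible pairs", {
  m <- tiny_model()  # non-orphans R1(g1), R2(g2,g3), R4(g4,g5)
  expect_equal(assignment_prior(m, c("g1", "g2", "g3", "g4", "g5")),
               5 / (5 * 3))
  expect_equal(assignment_prior(m, c("g1", "zz")), 1 / (2 * 3))
})
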