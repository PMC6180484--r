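test_that("binomial upper tails are exact and inclusive", {
  expect_equal(binom_tail(48, 0.25, 0), 1)
  expect_equal(binom_tail(48, 0.25, 48), 0.25^48)
  expect_equal(binom_tail(48, 0.25, 30), 4.41e-8, tolerance = 5e-3)
  expect_equal(binom_tail(48, 1 / 7, 36), 4.37e-21, tolerance = 5e-3)
  # monotone decreasing in k
  tails <- vapply(0:48, function(k) binom_tail(48, 0.25, k), 0)
  expect_true(all(diff(tails) < 0))
  expect_error(binom_tail(10, 1.2, 3), "p must")
  expect_error(binom_tail(10, 0.5, 11), "k must")
})

test_that("region-effect wins follow the per-condition argmin", {
  # focal kind lowest in every one of 10 conditions, 4 kinds
  mats <- list(
    utr3 = pm(matrix(-5, 2, 10)),
    cds = pm(matrix(0, 2, 10)),
    utr5 = pm(matrix(1, 2, 10)),
    prom = pm(matrix(2, 2, 10))
  )
  out <- region_effect_test(mats, "utr3")
  expect_equal(out$wins, 10)
  expect_equal(out$p_value, 0.25^10)
  # random matrices: wins equals a brute-force recount
  set.seed(61)
  mats2 <- lapply(1:4, function(i) pm(matrix(rnorm(40), 4, 10)))
  names(mats2) <- paste0("k", 1:4)
  out2 <- region_effect_test(mats2, "k2", statistic = "median")
  manual <- sum(vapply(1:10, function(j) {
    meds <- vapply(mats2, function(m) median(m[, j]), 0)
    meds["k2"] == min(meds)
  }, TRUE))
  expect_equal(out2$wins, manual)
  expect_equal(out2$p_value, binom_tail(10, 0.25, manual))
  # conditions with a missing kind are skipped and reported
  mats3 <- mats2
  mats3$k1[, 3] <- NA
  out3 <- region_effect_test(mats3, "k2")
  expect_equal(out3$n_conditions, 9)
  expect_equal(out3$n_skipped, 1)
})

test_that("cofitness matrices match a rank-then-Pearson oracle", {
  m <- pm(matrix(c(1, 2, 3, 4,
                   4, 3, 2, 1,
                   1, 2, 3, 4), 3, 4, byrow = TRUE))
  cf <- cofitness_matrix(m)
  expect_equal(cf[1, 2], -1)
  expect_equal(cf[1, 3], 1)
  expect_equal(diag(cf), rep(1, 3), ignore_attr = TRUE)
  set.seed(67)
  m2 <- pm(matrix(rnorm(48), 8, 6))
  cf2 <- cofitness_matrix(m2)
  expect_equal(cf2, t(cf2))
  for (i in 1:7) {
    for (j in (i + 1):8) {
      oracle <- cor(rank(m2[i, ]), rank(m2[j, ]))
      expect_equal(cf2[i, j], oracle, tolerance = 1e-12)
    }
  }
  # insufficient overlap yields NA
  m3 <- pm(matrix(c(1, 2, NA, NA, NA, NA, 3, 4), 2, 4, byrow = TRUE))
  expect_true(is.na(cofitness_matrix(m3)[1, 2]))
})

test_that("rank-sum enrichment matches exact enumeration for small samples", {
  # against R's exact Wilcoxon when there are no ties
  set.seed(71)
  for (i in 1:20) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- class_enrichment(x, y)$p_value
    ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # with ties: independent enumeration by direct pair counting
  x <- c(2, 2, 5); y <- c(1, 2, 2, 4)
  ours <- class_enrichment(x, y)$p_value
  pooled <- c(x, y)
  u_obs <- u_by_counting(x, y)
  combos <- combn(7, 3)
  u_all <- apply(combos, 2, function(idx) {
    u_by_counting(pooled[idx], pooled[-idx])
  })
  expect_equal(ours, mean(u_all >= u_obs - 1e-9))
})

test_that("rank-sum enrichment behaves under null and shifted alternatives", {
  expect_warning(out <- class_enrichment(c(1, 2), c(0, 3, 1)), "fewer than 3")
  set.seed(73)
  # null: class drawn from the background distribution -> p roughly uniform
  p_null <- replicate(200, {
    class_enrichment(rnorm(15), rnorm(40), exact_limit = 0)$p_value
  })
  expect_gt(mean(p_null), 0.4); expect_lt(mean(p_null), 0.6)
  # strong shift at n = 100 -> small p in nearly all runs
  p_shift <- replicate(100, {
    class_enrichment(rnorm(100, 1), rnorm(100), exact_limit = 0)$p_value
  })
  expect_gte(mean(p_shift < 0.01), 0.95)
  # top decile of the background is clearly enriched
  bg <- seq(0, 1, length.out = 50)
  expect_lt(class_enrichment(tail(bg, 5), head(bg, 45))$p_value, 0.01)
})

test_that("relative ratio curves match direct counting", {
  bg <- seq(-0.4, 0.9, length.out = 20)
  ident <- relative_ratio_curve(bg, bg)
  expect_equal(ident$log10_ratio[ident$flag == "ok"],
               rep(0, sum(ident$flag == "ok")), tolerance = 1e-12)
  # thresholds above every value are undefined (background fraction 0)
  expect_true(all(ident$flag[ident$x > max(bg)] == "undefined"))
  # x below every value -> both fractions 1 -> ratio 0
  out <- relative_ratio_curve(c(0.2, 0.5), c(0.1, 0.9), xs = -0.5)
  expect_equal(out$log10_ratio, 0)
  # hand-built 6-pair class vs 20-pair background at x = 0.5
  cl <- c(0.9, 0.8, 0.6, 0.4, 0.2, -0.1)
  out2 <- relative_ratio_curve(cl, bg, xs = 0.5)
  expect_equal(out2$log10_ratio,
               log10((sum(cl >= 0.5) / 6) / (sum(bg >= 0.5) / 20)))
  # empty class tail is flagged rather than -Inf
  out3 <- relative_ratio_curve(c(0.1, 0.2), bg, xs = 0.8)
  expect_equal(out3$flag, "class_empty")
  expect_true(is.na(out3$log10_ratio))
})

test_that("distance bins and the GC-decile filter stratify pairs correctly", {
  genes <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    start = c(1000, 4500, 20000, 21000),
    gc = c(0.30, 0.52, 0.51, 0.70)
  )
  out <- stratify_pairs(genes, bin_sizes = 5e3, gc_bins = 2)
  # a-b within 5kb and in different GC halves
  expect_true(any(out$gene_a == "a" & out$gene_b == "b"))
  # c-d within 5kb and in different GC halves -> kept
  expect_true(any(out$gene_a == "c" & out$gene_b == "d"))
  # a and c share the low-GC half: the pair is filtered at any distance
  out_all <- stratify_pairs(dplyr::mutate(genes, start = 0), bin_sizes = 1e5,
                            gc_bins = 2)
  expect_false(any(out_all$gene_a == "a" & out_all$gene_b == "c"))
  expect_false(any(out_all$gene_a == "b" & out_all$gene_b == "d"))
  # brute-force distance check on a random fixture
  set.seed(79)
  genesR <- tibble::tibble(id = sprintf("g%02d", 1:15),
                           start = sample.int(50000, 15))
  outR <- stratify_pairs(genesR, bin_sizes = c(5e3, 2e4))
  for (bs in c(5e3, 2e4)) {
    got <- outR[outR$class == paste0("distance_bin:",
                                     format(bs, scientific = FALSE, trim = TRUE)), ]
    manual <- 0L
    for (i in 1:14) {
      for (j in (i + 1):15) {
        if (abs(genesR$start[i] - genesR$start[j]) <= bs) manual <- manual + 1L
      }
    }
    expect_equal(nrow(got), manual)
  }
  # pair extraction pulls the right correlations
  cf <- matrix(c(1, .5, .5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(pair_values(cf, tibble::tibble(gene_a = "a", gene_b = "b")), .5)
})
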