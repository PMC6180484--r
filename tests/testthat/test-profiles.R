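test_that("z_normalize centres and scales by the population sd", {
  m <- pm(matrix(c(1, 2, 3), ncol = 1))
  z <- z_normalize(m)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_true(is_normalized(z))
  # every column of a random matrix ends with mean 0, population sd 1
  set.seed(5)
  z2 <- z_normalize(pm(matrix(rnorm(500, 3, 2), 50, 10)))
  expect_equal(unname(colMeans(z2)), rep(0, 10), tolerance = 1e-9)
  expect_equal(unname(apply(z2, 2, function(x) sqrt(mean((x - mean(x))^2)))),
               rep(1, 10), tolerance = 1e-9)
  # idempotent up to tolerance
  expect_equal(unclass(z_normalize(z2)), unclass(z2), tolerance = 1e-9)
})

test_that("z_normalize propagates NA and rejects degenerate columns", {
  v <- matrix(c(1, NA, 3, 5), ncol = 1)
  z <- z_normalize(pm(v))
  expect_true(is.na(z[2, 1]))
  expect_error(z_normalize(pm(matrix(c(2, 2, 2), ncol = 1))), "zero spread")
  expect_error(z_normalize(pm(matrix(c(1, NA, NA), ncol = 1))), "fewer than 2")
})

test_that("condition_pair_score is an entry difference and antisymmetric", {
  m <- pm(matrix(c(2, 0.5), 1, 2, dimnames = list("p", c("ca", "cb"))))
  expect_equal(condition_pair_score(m, "p", "ca", "cb"), 1.5)
  expect_equal(condition_pair_score(m, "p", "ca", "ca"), 0)
  expect_equal(condition_pair_score(m, "p", "cb", "ca"),
               -condition_pair_score(m, "p", "ca", "cb"))
  expect_error(condition_pair_score(m, "nope", "ca", "cb"), "unknown element")
  expect_error(condition_pair_score(m, "p", "ca", "cz"), "unknown condition")
})

test_that("region fitness is the mean over insertions inside the interval", {
  ins <- tibble::tibble(position = c(5L, 7L, 9L, 20L), scaffold = "chr",
                        c1 = c(-1, 0, 2, 100))
  region <- list(scaffold = "chr", start = 5L, end = 10L)
  expect_equal(region_fitness(ins, region, "c1"), 1 / 3)
  # half-open: position == end excluded, position == start included
  expect_equal(region_fitness(ins, list(scaffold = "chr", start = 9L, end = 20L), "c1"), 2)
  expect_true(is.na(region_fitness(ins, list(scaffold = "chr", start = 50L, end = 60L), "c1")))
  expect_error(region_fitness(ins, region, "c9"), "unknown condition")
  # permutation invariance and brute-force agreement on random data
  set.seed(9)
  ins2 <- tibble::tibble(position = sample(0:999, 100), scaffold = "chr",
                         c1 = rnorm(100))
  r2 <- list(scaffold = "chr", start = 123L, end = 456L)
  manual <- mean(ins2$c1[ins2$position >= 123 & ins2$position < 456])
  expect_equal(region_fitness(ins2, r2, "c1"), manual)
  expect_equal(region_fitness(ins2[sample(100), ], r2, "c1"), manual)
})

test_that("region_fitness_matrix fills a region-by-condition profile", {
  ins <- tibble::tibble(position = c(1L, 2L, 11L), scaffold = "chr",
                        c1 = c(1, 3, 5), c2 = c(NA, NA, 7))
  regions <- tibble::tibble(scaffold = "chr", start = c(0L, 10L),
                            end = c(10L, 20L), id = c("ra", "rb"),
                            kind = "promoter", strand = "+")
  m <- region_fitness_matrix(ins, regions)
  expect_equal(m["ra", "c1"], 2)
  expect_true(is.na(m["ra", "c2"]))
  expect_equal(m["rb", "c2"], 7)
})

test_that("ranked promoter lists sort ascending with lexicographic ties", {
  m <- pm(matrix(c(-2, 0, -1), 3, 1,
                 dimnames = list(c("pA", "pB", "pC"), "c1")))
  regions <- tibble::tibble(scaffold = "chr", start = 0L, end = 10L,
                            id = c("pA", "pB", "pC"), kind = "promoter",
                            strand = "+", gene = NA, sigma = NA,
                            sequence = c("ACGT", "ACGT", "ACGT"))
  out <- ranked_promoter_list(m, regions, "c1")
  expect_equal(out$id, c("pA", "pC", "pB"))
  # all-equal scores fall back to id order
  m2 <- pm(matrix(0, 3, 1, dimnames = list(c("pC", "pA", "pB"), "c1")))
  regions2 <- dplyr::mutate(regions, id = c("pC", "pA", "pB"))
  expect_equal(ranked_promoter_list(m2, regions2, "c1")$id,
               c("pA", "pB", "pC"))
  # promoters without sequence excluded with a warning
  regions3 <- dplyr::mutate(regions, sequence = c("ACGT", NA, "ACGT"))
  expect_warning(out3 <- ranked_promoter_list(m, regions3, "c1"), "excluded")
  expect_equal(out3$id, c("pA", "pC"))
  # matches an independent sort on random scores
  set.seed(21)
  sc <- matrix(rnorm(26), 26, 1,
               dimnames = list(paste0("p", letters), "c1"))
  regionsR <- tibble::tibble(scaffold = "chr", start = 0L, end = 10L,
                             id = rownames(sc), kind = "promoter",
                             strand = "+", gene = NA, sigma = NA,
                             sequence = "ACGT")
  expect_equal(ranked_promoter_list(pm(sc), regionsR, "c1")$id,
               rownames(sc)[order(sc[, 1], rownames(sc))])
})

test_that("profile TSV and FASTA writers round-trip", {
  m <- pm(matrix(rnorm(12), 3, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(m, path)
  m2 <- read_profile_tsv(path)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)
  ranked <- tibble::tibble(id = c("p1", "p2"), score = c(-1, 0),
                           sequence = c("ACGT", "GGCC"))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_ranked_fasta(ranked, fa)
  lines <- readLines(fa)
  expect_equal(lines[c(2, 4)], c("ACGT", "GGCC"))
  expect_match(lines[1], "^>p1")
})

test_that("build_vectors preserves condition order and checks ids", {
  m <- pm(matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z"))))
  v <- build_vectors(m, c("b", "a"))
  expect_equal(v$b, c(x = 2, y = 4, z = 6))
  expect_error(build_vectors(m, "q"), "unknown id")
})
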