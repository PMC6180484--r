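#' Exact upper tail of a binomial distribution
#'
#' `P(X >= k)` for `X ~ Binomial(n, p)`, inclusive at `k`.  This is the
#' null p-value for observing `k` wins out of `n` trials when each trial
#' succeeds with probability `p`.
#'
#' @param n Number of trials.
#' @param p Success probability, in (0, 1).
#' @param k Observed count, `0 <= k <= n`.
#' @return The inclusive upper-tail probability.
#' @examples
#' binom_tail(48, 0.25, 30)   # ~4.4e-8
#' @export
binom_tail <- function(n, p, k) {
  if (p <= 0 || p >= 1) stop("p must be in (0,1)", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in [0, n]", call. = FALSE)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Per-condition region-effect test
#'
#' For each condition, computes a location statistic of the fitness scores
#' within every region kind and counts the conditions in which the focal
#' kind is the most negative ("wins").  Under the null that each of the
#' `n_kinds` kinds is equally likely to win, the p-value is the inclusive
#' binomial upper tail at the observed win count with `p = 1/n_kinds`.
#'
#' @param kind_matrices Named list of [profile_matrix] objects, one per
#'   region kind, sharing condition columns.
#' @param focal_kind Name of the kind tested for stronger negative effect.
#' @param statistic One of `"mean"`, `"pct10"`, `"pct25"`, `"median"`.
#' @return A one-row tibble with `wins`, `n_conditions` (conditions where
#'   every kind had data; others are skipped and counted in
#'   `n_skipped`), `n_kinds` and `p_value`.
#' @export
region_effect_test <- function(kind_matrices, focal_kind,
                               statistic = c("mean", "pct10", "pct25",
                                             "median")) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(kind_matrices), focal_kind %in% names(kind_matrices))
  if (length(kind_matrices) < 2) stop("need >= 2 region kinds", call. = FALSE)
  stat_fun <- switch(statistic,
    mean = function(x) mean(x),
    pct10 = function(x) stats::quantile(x, 0.10, names = FALSE),
    pct25 = function(x) stats::quantile(x, 0.25, names = FALSE),
    median = function(x) stats::median(x)
  )
  conds <- Reduce(intersect, lapply(kind_matrices, colnames))
  wins <- 0L; used <- 0L; skipped <- 0L
  for (cc in conds) {
    vals <- vapply(kind_matrices, function(m) {
      x <- m[, cc]
      x <- x[is.finite(x)]
      if (length(x) == 0) NA_real_ else stat_fun(x)
    }, 0)
    if (anyNA(vals)) {
      skipped <- skipped + 1L
      next
    }
    used <- used + 1L
    if (vals[focal_kind] == min(vals) && sum(vals == min(vals)) == 1L) {
      wins <- wins + 1L
    }
  }
  if (used == 0) stop("no condition with data in every kind", call. = FALSE)
  n_kinds <- length(kind_matrices)
  tibble::tibble(
    focal_kind = focal_kind, statistic = statistic,
    wins = wins, n_conditions = used, n_skipped = skipped,
    n_kinds = n_kinds,
    p_value = binom_tail(used, 1 / n_kinds, wins)
  )
}

# --- rank-sum enrichment ---------------------------------------------------

#' One-tailed Wilcoxon rank-sum enrichment of a class of pair values
#'
#' Tests whether the co-fitness (or co-expression) values of a functional
#' class of gene pairs are stochastically greater than a background of pair
#' values.  The background must already exclude the class pairs (and, for
#' non-operon classes, same-operon pairs).  Exact enumeration of all rank
#' assignments is used for small samples (`n1 + n2 <= exact_limit`, or
#' whenever the class has fewer than 3 values, with a warning); larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param class_values Numeric vector of pair values in the class.
#' @param background_values Numeric vector of background pair values.
#' @param exact_limit Largest `n1 + n2` handled by exact enumeration
#'   (default 10).
#' @return One-row tibble with `n_class`, `n_background`, `statistic`
#'   (Mann-Whitney U of the class) and `p_value` for the alternative
#'   "class > background".
#' @export
class_enrichment <- function(class_values, background_values,
                             exact_limit = 10L) {
  x <- class_values[is.finite(class_values)]
  y <- background_values[is.finite(background_values)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (length(x) < 3) {
    warning("class has fewer than 3 values; exact enumeration used",
            call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (n1 + n2 <= exact_limit || n1 < 3) {
    exact_ranksum_p(r, n1, u_obs)
  } else {
    normal_ranksum_p(r, n1, n2, u_obs)
  }
  tibble::tibble(n_class = n1, n_background = n2,
                 statistic = u_obs, p_value = p)
}

# exact one-sided P(U >= u_obs) by enumerating every class/background split
# of the pooled ranks
exact_ranksum_p <- function(pooled_ranks, n1, u_obs) {
  n <- length(pooled_ranks)
  offset <- n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) sum(pooled_ranks[idx])) - offset
  mean(u_all >= u_obs - 1e-9)
}

normal_ranksum_p <- function(pooled_ranks, n1, n2, u_obs) {
  n <- n1 + n2
  ties <- table(pooled_ranks)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u_obs - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Relative survival-ratio curve for a class of pair values
#'
#' For each threshold `x`, the fraction of class pairs with value `>= x` is
#' divided by the corresponding background fraction and reported as a
#' log10 ratio; positive values mean the class is enriched for high
#' co-fitness above `x`.
#'
#' @param class_values,background_values Numeric pair-value vectors.
#' @param xs Threshold grid (default `seq(-0.5, 1, by = 0.05)`).
#' @return Tibble with `x`, `frac_class`, `frac_background`, `log10_ratio`
#'   and a `flag` column: `"ok"`, `"class_empty"` (class fraction 0, ratio
#'   undefined at -Inf) or `"undefined"` (background fraction 0).
#' @export
relative_ratio_curve <- function(class_values, background_values,
                                 xs = seq(-0.5, 1, by = 0.05)) {
  x <- class_values[is.finite(class_values)]
  y <- background_values[is.finite(background_values)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  fc <- vapply(xs, function(t) mean(x >= t), 0)
  fb <- vapply(xs, function(t) mean(y >= t), 0)
  flag <- dplyr::case_when(fb == 0 ~ "undefined",
                           fc == 0 ~ "class_empty",
                           TRUE ~ "ok")
  tibble::tibble(
    x = xs, frac_class = fc, frac_background = fb,
    log10_ratio = ifelse(flag == "ok", log10(fc / fb), NA_real_),
    flag = flag
  )
}

#' Stratify gene pairs by genomic distance, with a GC-content filter
#'
#' Builds distance-bin classes of gene pairs (start-to-start distance at
#' most the bin size, same scaffold; cross-replicon pairs are excluded) and
#' optionally removes pairs whose two genes fall in the same GC-content
#' decile, a guard against co-fitness driven by shared base composition.
#'
#' @param genes Tibble with columns `id`, `start`, and optionally
#'   `scaffold` (single replicon assumed when absent) and `gc`
#'   (CDS GC fraction, required for the GC filter).
#' @param bin_sizes Distance thresholds in bp
#'   (default `c(5e3, 1e4, 2e4, 5e4, 1e5)`).
#' @param gc_filter Apply the same-GC-decile filter (default `TRUE` when a
#'   `gc` column is present).
#' @param gc_bins Number of GC quantile bins (default 10).
#' @return Tibble with `class` (e.g. `"distance_bin:5000"`), `gene_a`,
#'   `gene_b` (unordered, `gene_a < gene_b`).
#' @export
stratify_pairs <- function(genes, bin_sizes = c(5e3, 1e4, 2e4, 5e4, 1e5),
                           gc_filter = "gc" %in% names(genes),
                           gc_bins = 10L) {
  stopifnot(all(c("id", "start") %in% names(genes)))
  if (!"scaffold" %in% names(genes)) genes$scaffold <- "chr"
  if (gc_filter && !"gc" %in% names(genes)) {
    stop("GC filter requested but no `gc` column", call. = FALSE)
  }
  gc_bin <- if (gc_filter) {
    breaks <- unique(stats::quantile(genes$gc, probs = seq(0, 1,
                                                           length.out = gc_bins + 1)))
    as.integer(cut(genes$gc, breaks = breaks, include.lowest = TRUE,
                   right = TRUE))
  } else rep(NA_integer_, nrow(genes))

  pairs <- tidyr::crossing(i = seq_len(nrow(genes)), j = seq_len(nrow(genes))) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      gene_a = pmin(genes$id[.data$i], genes$id[.data$j]),
      gene_b = pmax(genes$id[.data$i], genes$id[.data$j]),
      same_scaffold = genes$scaffold[.data$i] == genes$scaffold[.data$j],
      dist = abs(genes$start[.data$i] - genes$start[.data$j]),
      same_gc = gc_filter & gc_bin[.data$i] == gc_bin[.data$j]
    ) |>
    dplyr::filter(.data$same_scaffold, !.data$same_gc)

  purrr::map_dfr(bin_sizes, function(bs) {
    pairs |>
      dplyr::filter(.data$dist <= bs) |>
      dplyr::transmute(class = paste0("distance_bin:", format(bs, scientific = FALSE,
                                                              trim = TRUE)),
                       gene_a = .data$gene_a, gene_b = .data$gene_b)
  })
}

#' Extract pair values from a symmetric correlation matrix
#'
#' @param cof Symmetric matrix from [cofitness_matrix()].
#' @param pairs Tibble with `gene_a`, `gene_b` columns; pairs with ids
#'   outside the matrix are dropped.
#' @return Numeric vector of correlations, one per retained pair.
#' @export
pair_values <- function(cof, pairs) {
  keep <- pairs$gene_a %in% rownames(cof) & pairs$gene_b %in% rownames(cof)
  pairs <- pairs[keep, ]
  cof[cbind(pairs$gene_a, pairs$gene_b)]
}
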