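#' Minimum hypergeometric (mHG) statistic of a ranked binary list
#'
#' Given a 0/1 vector ordered by some ranking (best first), the mHG score is
#' the smallest hypergeometric upper-tail probability `P(X >= b(n))`, over
#' all prefixes `n`, of seeing `b(n)` ones in a prefix of length `n` when
#' `B` ones are spread over `N` positions at random.  Small scores mean the
#' ones concentrate at the top of the ranking.  The score is a statistic,
#' not a corrected p-value.
#'
#' @param labels Integer/logical 0-1 vector in rank order.
#' @return One-row tibble with `score`, `n` and `b` at the minimizing
#'   prefix (first such prefix on ties); `score = 1` with `n = b = 0` when
#'   the list has no ones.
#' @examples
#' mhg(c(1, 0, 0, 0))  # score 0.25 at n = 1
#' @export
mhg <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0 || any(!labels %in% c(0L, 1L))) {
    stop("`labels` must be a non-empty 0/1 vector", call. = FALSE)
  }
  N <- length(labels)
  B <- sum(labels)
  if (B == 0L) {
    return(tibble::tibble(score = 1, n = 0L, b = 0L, N = N, B = B))
  }
  b_at <- cumsum(labels)
  n_seq <- seq_len(N)
  tails <- stats::phyper(b_at - 1, B, N - B, n_seq, lower.tail = FALSE)
  i <- which.min(tails)
  tibble::tibble(score = tails[i], n = n_seq[i], b = b_at[i], N = N, B = B)
}

#' Mutual mHG (mmHG) between two rankings of the same elements
#'
#' Measures whether the tops of two rankings overlap: for every threshold
#' `B` on the first ranking, the top-`B` elements are taken as the 1-labels
#' and scored with [mhg()] along the second ranking; the mmHG score is the
#' minimum over thresholds.  An empirical p-value is obtained by shuffling
#' the first ranking and recomputing the score.
#'
#' @param rank_a,rank_b Character vectors: the same element ids in two rank
#'   orders (best first).
#' @param n_shuffles Number of shuffles for the empirical p-value
#'   (default 100; 0 skips it).
#' @param seed Optional integer seed for the shuffles.
#' @return One-row tibble with `score`, `N`, `B`, `n`, `b` at the optimum
#'   and `p_empirical` (fraction of shuffles with score <= observed; `NA`
#'   if `n_shuffles = 0`).
#' @export
mmhg_pair <- function(rank_a, rank_b, n_shuffles = 100L, seed = NULL) {
  if (length(rank_a) != length(rank_b) ||
      !setequal(rank_a, rank_b) || anyDuplicated(rank_a)) {
    stop("`rank_a` and `rank_b` must order the same distinct elements",
         call. = FALSE)
  }
  obs <- mmhg_score(rank_a, rank_b)
  p <- NA_real_
  if (n_shuffles > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    null_scores <- vapply(seq_len(n_shuffles), function(i) {
      mmhg_score(sample(rank_a), rank_b)$score
    }, 0)
    p <- mean(null_scores <= obs$score)
  }
  dplyr::mutate(obs, p_empirical = p)
}

mmhg_score <- function(rank_a, rank_b) {
  N <- length(rank_a)
  best <- NULL
  for (B in seq_len(max(1L, N - 1L))) {
    top <- rank_a[seq_len(B)]
    labels <- as.integer(rank_b %in% top)
    m <- mhg(labels)
    if (is.null(best) || m$score < best$score) {
      best <- dplyr::mutate(m, B_threshold = B)
    }
  }
  tibble::tibble(score = best$score, N = N, B = best$B_threshold,
                 n = best$n, b = best$b)
}

# --- PSSM scanning ---------------------------------------------------------

#' Log-odds transform of a position probability matrix
#'
#' @param pssm 4 x w numeric matrix, rows named `A`, `C`, `G`, `T`, columns
#'   positions; entries are base probabilities (columns sum to 1).
#' @param pseudocount Added to probabilities before the log (default 1e-3).
#' @param background Background base probability (uniform, 0.25).
#' @return 4 x w matrix of log2 odds scores.
#' @export
pssm_log_odds <- function(pssm, pseudocount = 1e-3, background = 0.25) {
  stopifnot(is.matrix(pssm), nrow(pssm) == 4,
            setequal(rownames(pssm), c("A", "C", "G", "T")))
  log2((pssm[c("A", "C", "G", "T"), , drop = FALSE] + pseudocount) /
         (background + pseudocount))
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, "", USE.NAMES = FALSE))
}

#' Best PSSM match score of a sequence (both strands)
#'
#' @param seq A nucleotide string (ACGT; other letters score as missing
#'   positions with the pseudocount background).
#' @param log_odds Matrix from [pssm_log_odds()].
#' @return Maximum over all windows on both strands of the summed log-odds,
#'   or `NA` when the sequence is shorter than the motif.
#' @export
pssm_best_score <- function(seq, log_odds) {
  w <- ncol(log_odds)
  score_strand <- function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    L <- length(chars)
    if (L < w) return(NA_real_)
    best <- -Inf
    for (start in seq_len(L - w + 1)) {
      win <- chars[start:(start + w - 1)]
      idx <- match(win, c("A", "C", "G", "T"))
      if (anyNA(idx)) next
      sc <- sum(log_odds[cbind(idx, seq_len(w))])
      if (sc > best) best <- sc
    }
    if (is.infinite(best)) NA_real_ else best
  }
  max(score_strand(seq), score_strand(revcomp(seq)), na.rm = FALSE)
}

#' Motif enrichment at the top of a fitness-ranked promoter list
#'
#' Scores every promoter sequence with the PSSM (best window, both
#' strands), calls promoters above `hit_threshold` motif hits, and measures
#' whether hits concentrate at the top of the fitness ranking with [mhg()].
#'
#' @param ranked Tibble from [ranked_promoter_list()] (`id`, `score`,
#'   `sequence`), already in rank order.
#' @param pssm Position probability matrix (see [pssm_log_odds()]).
#' @param hit_threshold Log2-odds score at or above which a promoter is a
#'   hit.
#' @return List with `hits` (tibble `id`, `max_score`, `hit`, rank order
#'   preserved; promoters shorter than the motif are dropped with a
#'   warning) and `mhg` (one-row tibble from [mhg()]).
#' @export
pssm_enrichment <- function(ranked, pssm, hit_threshold) {
  lo <- pssm_log_odds(pssm)
  scores <- vapply(ranked$sequence, pssm_best_score, 0, log_odds = lo,
                   USE.NAMES = FALSE)
  short <- is.na(scores)
  if (any(short)) {
    warning(sum(short), " promoter(s) shorter than the motif skipped",
            call. = FALSE)
  }
  hits <- tibble::tibble(
    id = ranked$id[!short],
    max_score = scores[!short],
    hit = scores[!short] >= hit_threshold
  )
  enrich <- if (nrow(hits) == 0) {
    tibble::tibble(score = 1, n = 0L, b = 0L, N = 0L, B = 0L)
  } else {
    mhg(as.integer(hits$hit))
  }
  list(hits = hits, mhg = enrich)
}
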