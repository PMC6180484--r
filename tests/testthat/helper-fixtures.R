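# Shared builders for hand-sized fixtures.  Everything is constructed in
# code; no data files.

# linear chain R1 -> R2 -> R3 (R3 orphan) plus a detached reaction
tiny_model <- function() {
  metabolic_model(tibble::tibble(
    id = c("R1", "R2", "R3", "R4"),
    stoich = list(
      c(A = -1, B = 1),
      c(B = -1, C = 1),
      c(C = -1, D = 1),
      c(E = -1, F = 1)
    ),
    gpr = list(parse_gpr("g1"), parse_gpr("g2 and g3"), NULL,
               parse_gpr("g4 or g5"))
  ))
}

# star model: orphan RO shares one private species with each neighbor
star_model <- function(n_neighbors = 3) {
  nb <- sprintf("N%d", seq_len(n_neighbors))
  rx <- tibble::tibble(
    id = c("RO", nb),
    stoich = c(
      list(stats::setNames(rep(-1, n_neighbors), paste0("m", seq_len(n_neighbors)))),
      lapply(seq_len(n_neighbors), function(i) {
        stats::setNames(c(1, -1), c(paste0("m", i), paste0("x", i)))
      })
    ),
    gpr = c(list(NULL), lapply(seq_len(n_neighbors), function(i) {
      parse_gpr(sprintf("ng%d", i))
    }))
  )
  metabolic_model(rx)
}

# random DNF as a clause list over a gene pool
random_dnf <- function(n_genes = 4, max_clauses = 3) {
  genes <- sprintf("g%d", seq_len(n_genes))
  n_clauses <- sample(max_clauses, 1)
  clauses <- lapply(seq_len(n_clauses), function(i) {
    sample(genes, sample(n_genes, 1))
  })
  gpr(clauses)
}

# random nested boolean expression string + R-evaluable equivalent
random_bool_expr <- function(genes, depth = 2) {
  if (depth == 0 || stats::runif(1) < 0.3) {
    return(sample(genes, 1))
  }
  op <- sample(c("and", "or"), 1)
  left <- random_bool_expr(genes, depth - 1)
  right <- random_bool_expr(genes, depth - 1)
  paste0("(", left, " ", op, " ", right, ")")
}

eval_bool_string <- function(text, status) {
  expr <- gsub("\\band\\b", "&", text)
  expr <- gsub("\\bor\\b", "|", expr)
  for (g in names(status)) {
    expr <- gsub(paste0("\\b", g, "\\b"), as.character(status[[g]]), expr)
  }
  eval(parse(text = expr))
}

# profile matrix from a plain matrix with auto names
pm <- function(values, normalized = FALSE) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("r%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  }
  profile_matrix(values, normalized = normalized)
}

# inclusive hypergeometric upper tail by summing point masses (independent
# of phyper)
hyper_tail <- function(b, B, N, n) {
  ks <- b:min(n, B)
  if (b > min(n, B)) return(0)
  sum(stats::dhyper(ks, B, N - B, n))
}

# Mann-Whitney U of x vs y by direct pair counting (independent of ranks)
u_by_counting <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
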