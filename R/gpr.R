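#' Gene-protein-reaction (GPR) boolean rules
#'
#' A GPR rule states which combinations of genes activate a reaction:
#' isozymes are alternatives (OR) and complex subunits are jointly required
#' (AND).  Internally every rule is held in disjunctive normal form (DNF),
#' an OR over protein clauses where each clause is the AND (a set) of the
#' genes encoding one catalysing protein.
#'
#' @param clauses A list of character vectors, one vector of gene ids per
#'   protein clause.  Empty clauses are an error; duplicate genes within a
#'   clause and duplicate clauses are collapsed.
#' @return An object of class `gpr`: a list of sorted character vectors.
#' @examples
#' gpr(list("g1", c("g2", "g3")))
#' parse_gpr("g1 or (g2 and g3)")
#' @export
gpr <- function(clauses) {
  if (!is.list(clauses) || length(clauses) == 0) {
    stop("a GPR needs at least one clause", call. = FALSE)
  }
  clauses <- lapply(clauses, function(cl) {
    cl <- unique(trimws(as.character(cl)))
    if (length(cl) == 0 || any(!nzchar(cl))) {
      stop("empty GPR clause", call. = FALSE)
    }
    sort(cl)
  })
  # canonical order: by serialized clause, so equal rule sets compare identical
  keys <- vapply(clauses, paste, "", collapse = "\r")
  clauses <- clauses[!duplicated(keys)]
  clauses <- clauses[order(keys[!duplicated(keys)])]
  structure(clauses, class = "gpr")
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Genes referenced by a GPR rule
#' @param x A [gpr] object.
#' @return Sorted character vector of gene ids.
#' @export
gpr_genes <- function(x) {
  stopifnot(inherits(x, "gpr"))
  sort(unique(unlist(x, use.names = FALSE)))
}

# --- tokenizer -------------------------------------------------------------

gpr_tokens <- function(text) {
  text <- gsub("&&", " and ", text, fixed = TRUE)
  text <- gsub("||", " or ", text, fixed = TRUE)
  text <- gsub("&", " and ", text, fixed = TRUE)
  text <- gsub("|", " or ", text, fixed = TRUE)
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a boolean GPR string into disjunctive normal form
#'
#' Accepts gene identifiers, parentheses and the connectives
#' `and`/`AND`/`&`/`&&` and `or`/`OR`/`|`/`||`.  Nested expressions are
#' expanded by distributing AND over OR, so `"(g1 or g2) and g3"` becomes
#' the two clauses `{g1,g3}` and `{g2,g3}`.
#'
#' @param text A GPR string, e.g. `"g1 or (g2 and g3)"`.  An empty or
#'   all-whitespace string is an error (use `NULL` for an orphan reaction).
#' @return A [gpr] object.
#' @export
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("`text` must be a single GPR string", call. = FALSE)
  }
  toks <- gpr_tokens(text)
  if (length(toks) == 0) stop("empty GPR expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  is_op <- function(t) !is.na(t) && tolower(t) %in% c("and", "or")
  # grammar: expr := term ('or' term)* ; term := factor ('and' factor)* ;
  #          factor := gene | '(' expr ')'
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR expression", call. = FALSE)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) {
        stop("unbalanced parentheses in GPR", call. = FALSE)
      }
      return(e)
    }
    if (t == ")" || is_op(t)) {
      stop("missing operand near '", t, "' in GPR", call. = FALSE)
    }
    list(t)
  }
  parse_term <- function() {
    clauses <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      rhs <- parse_factor()
      # AND of two DNFs: pairwise clause unions
      clauses <- unlist(
        lapply(clauses, function(a) lapply(rhs, function(b) union(a, b))),
        recursive = FALSE
      )
    }
    clauses
  }
  parse_expr <- function() {
    clauses <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      clauses <- c(clauses, parse_term())
    }
    clauses
  }
  out <- parse_expr()
  if (pos <= length(toks)) {
    stop("unbalanced parentheses in GPR near '", toks[pos], "'", call. = FALSE)
  }
  gpr(out)
}

#' Serialize a GPR rule back to a boolean string
#'
#' The output round-trips: `parse_gpr(gpr_to_string(x))` equals `x`.
#'
#' @param x A [gpr] object.
#' @return A single string, OR of parenthesised AND clauses.
#' @export
gpr_to_string <- function(x) {
  stopifnot(inherits(x, "gpr"))
  cl <- vapply(x, function(g) {
    if (length(g) == 1) g else paste0("(", paste(g, collapse = " and "), ")")
  }, "")
  paste(cl, collapse = " or ")
}

#' Evaluate a GPR rule under a gene activity assignment
#'
#' @param x A [gpr] object.
#' @param status Named logical vector; `TRUE` means the gene is active.
#'   Every gene of the rule must be present.
#' @return `TRUE` if some clause has all its genes active.
#' @export
evaluate_activity <- function(x, status) {
  stopifnot(inherits(x, "gpr"))
  genes <- gpr_genes(x)
  missing <- setdiff(genes, names(status))
  if (length(missing) > 0) {
    stop("no activity status for gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  any(vapply(x, function(cl) all(status[cl]), TRUE))
}
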