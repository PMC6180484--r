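#' Metabolic model container
#'
#' A light, tabular view of a genome-scale metabolic model: a reaction table
#' with stoichiometries and parsed GPR rules, a species table, and the set of
#' genes mentioned by any GPR.  Reactions without a GPR rule are *orphan*
#' reactions — reactions whose catalysing gene is unknown.
#'
#' @param reactions A tibble/data frame with columns `id` (character),
#'   `stoich` (list of named numeric vectors, species id -> signed
#'   coefficient), `gpr` (list of [gpr] objects or `NULL` for orphans) and
#'   optionally `reversible` (logical, informational).
#' @param species Optional tibble with columns `id` and `compartment`; if
#'   omitted it is derived from the stoichiometries (compartment taken from a
#'   trailing `_x` / `[x]` suffix when present, otherwise `""`).
#' @return An object of class `metabolic_model` with elements `reactions`
#'   (tibble), `species` (tibble with reference `frequency` counts) and
#'   `genes` (character).
#' @examples
#' m <- metabolic_model(tibble::tibble(
#'   id = c("R1", "R2"),
#'   stoich = list(c(A = -1, B = 1), c(B = -1, C = 1)),
#'   gpr = list(parse_gpr("g1"), NULL)
#' ))
#' orphan_reactions(m)
#' @export
metabolic_model <- function(reactions, species = NULL) {
  reactions <- tibble::as_tibble(reactions)
  if (nrow(reactions) == 0) stop("model has no reactions", call. = FALSE)
  stopifnot(all(c("id", "stoich", "gpr") %in% names(reactions)))
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids", call. = FALSE)
  }
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  ok <- vapply(reactions$stoich, function(s) {
    length(s) > 0 && !is.null(names(s)) && all(nzchar(names(s)))
  }, TRUE)
  if (!all(ok)) {
    stop("empty or unnamed stoichiometry in reaction(s): ",
         paste(reactions$id[!ok], collapse = ", "), call. = FALSE)
  }
  ok <- vapply(reactions$gpr, function(g) is.null(g) || inherits(g, "gpr"), TRUE)
  if (!all(ok)) stop("`gpr` column must hold gpr objects or NULL", call. = FALSE)

  used <- sort(unique(unlist(lapply(reactions$stoich, names))))
  if (is.null(species)) {
    species <- tibble::tibble(id = used, compartment = guess_compartment(used))
  } else {
    species <- tibble::as_tibble(species)
    stopifnot("id" %in% names(species))
    if (!"compartment" %in% names(species)) species$compartment <- ""
    if (anyDuplicated(species$id)) stop("duplicate species ids", call. = FALSE)
    missing <- setdiff(used, species$id)
    if (length(missing) > 0) {
      stop("species referenced but not declared: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  model <- structure(
    list(reactions = reactions, species = species[, c("id", "compartment")],
         genes = sort(unique(unlist(lapply(reactions$gpr, function(g) {
           if (is.null(g)) character() else gpr_genes(g)
         }))))),
    class = "metabolic_model"
  )
  model$species$frequency <-
    metabolite_frequencies(model)[model$species$id]
  model
}

guess_compartment <- function(ids) {
  comp <- rep("", length(ids))
  hit <- grepl("_[a-z]$", ids)
  comp[hit] <- sub("^.*_([a-z])$", "\\1", ids[hit])
  hit2 <- grepl("\\[[a-z]\\]$", ids)
  comp[hit2] <- sub("^.*\\[([a-z])\\]$", "\\1", ids[hit2])
  comp
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions (",
      sum(is_orphan(x)), " orphan), ", nrow(x$species), " species, ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Orphan status of every reaction
#'
#' A reaction is orphan iff it carries no GPR rule.
#'
#' @param model A [metabolic_model].
#' @return Named logical vector over reaction ids.
#' @export
is_orphan <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  out <- vapply(model$reactions$gpr, is.null, TRUE)
  names(out) <- model$reactions$id
  out
}

#' @rdname is_orphan
#' @return `orphan_reactions()`: character vector of orphan reaction ids.
#' @export
orphan_reactions <- function(model) {
  names(which(is_orphan(model)))
}

#' Count, for every species, the reactions whose stoichiometry uses it
#'
#' High-frequency ("currency") metabolites such as water or protons appear in
#' very many reactions and are candidates for removal before neighborhood
#' analysis.  Coefficient sign and magnitude are ignored; only non-zero
#' presence counts.
#'
#' @param model A [metabolic_model].
#' @return Named integer vector over all model species (0 for species never
#'   referenced).
#' @export
metabolite_frequencies <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  used <- unlist(lapply(model$reactions$stoich, function(s) names(s)[s != 0]))
  counts <- table(used)
  out <- stats::setNames(integer(nrow(model$species)), model$species$id)
  out[names(counts)] <- as.integer(counts)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metabolic model into one row per reaction
#'
#' @param x A [metabolic_model].
#' @param ... Unused.
#' @return A tibble with reaction id, orphan flag, GPR string, gene count and
#'   species count.
#' @export
tidy.metabolic_model <- function(x, ...) {
  tibble::tibble(
    id = x$reactions$id,
    orphan = unname(is_orphan(x)),
    gpr = vapply(x$reactions$gpr, function(g) {
      if (is.null(g)) NA_character_ else gpr_to_string(g)
    }, ""),
    n_genes = vapply(x$reactions$gpr, function(g) {
      if (is.null(g)) 0L else length(gpr_genes(g))
    }, 0L),
    n_species = lengths(x$reactions$stoich)
  )
}

#' @export
glance.metabolic_model <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$reactions),
    n_orphan = sum(is_orphan(x)),
    n_species = nrow(x$species),
    n_genes = length(x$genes),
    avg_genes_per_reaction = mean_genes_per_reaction(x)
  )
}

#' Average number of distinct GPR genes per non-orphan reaction
#'
#' The per-reaction gene multiplicity that feeds the strong uniform baseline
#' ([strong_udist]).
#'
#' @param model A [metabolic_model].
#' @return A single number (NA if the model has no non-orphan reaction).
#' @export
mean_genes_per_reaction <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  g <- model$reactions$gpr[!is_orphan(model)]
  if (length(g) == 0) return(NA_real_)
  mean(vapply(g, function(x) length(gpr_genes(x)), 0L))
}

# --- readers / writers -----------------------------------------------------

#' Read a metabolic model
#'
#' Dispatches on file extension: `.json` for the package's JSON dialect
#' (`{"reactions": [{"id", "metabolites": {id: coef}, "gpr": "...",
#' "reversible"}], "species": [{"id", "compartment"}]}`, with `"gpr"` absent,
#' empty or null for orphans) and `.xml`/`.sbml` for SBML (level 3 `fbc`
#' gene-product associations, or level 2 `GENE_ASSOCIATION:` notes).
#'
#' @param path Path to a model file.
#' @return A [metabolic_model].
#' @export
parse_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_model_json(path),
    xml = ,
    sbml = read_model_sbml(path),
    stop("unsupported model format: .", ext, call. = FALSE)
  )
}

#' @rdname parse_model
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$reactions) || length(raw$reactions) == 0) {
    stop("model has no reactions: ", path, call. = FALSE)
  }
  rx <- purrr::map(raw$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in ", path, call. = FALSE)
    stoich <- unlist(r$metabolites)
    g <- r$gpr
    gpr_obj <- if (is.null(g) || !nzchar(trimws(g))) NULL else {
      tryCatch(parse_gpr(g), error = function(e) {
        stop("bad GPR for reaction '", r$id, "': ", conditionMessage(e),
             call. = FALSE)
      })
    }
    tibble::tibble(
      id = trimws(r$id),
      stoich = list(stoich),
      gpr = list(gpr_obj),
      reversible = isTRUE(r$reversible)
    )
  })
  species <- if (!is.null(raw$species)) {
    purrr::map_dfr(raw$species, function(s) {
      tibble::tibble(id = s$id,
                     compartment = s$compartment %||% "")
    })
  } else NULL
  metabolic_model(dplyr::bind_rows(rx), species)
}

#' @rdname parse_model
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- if (length(sp_nodes) > 0) {
    tibble::tibble(
      id = xml2::xml_attr(sp_nodes, "id"),
      compartment = xml2::xml_attr(sp_nodes, "compartment") %|NA|% ""
    )
  } else NULL
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("model has no reactions: ", path, call. = FALSE)
  rx <- purrr::map_dfr(rx_nodes, function(node) {
    id <- trimws(xml2::xml_attr(node, "id"))
    refs <- function(xp, sign) {
      sr <- xml2::xml_find_all(node, xp)
      if (length(sr) == 0) return(numeric())
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %|NA|% "1")
      stats::setNames(sign * coef, xml2::xml_attr(sr, "species"))
    }
    stoich <- c(refs("./listOfReactants/speciesReference", -1),
                refs("./listOfProducts/speciesReference", +1))
    stoich <- tapply(stoich, names(stoich), sum)  # merge duplicate refs
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
    gpr_obj <- sbml_gpr(node, id)
    tibble::tibble(
      id = id, stoich = list(stoich), gpr = list(gpr_obj),
      reversible = identical(xml2::xml_attr(node, "reversible"), "true")
    )
  })
  model <- metabolic_model(rx, species)
  # fbc geneProduct ids may be labels; prefer fbc:label when declared
  model
}

# Extract a GPR from an SBML reaction node: fbc association subtree if
# present, else a "GENE_ASSOCIATION: ..." line in the notes.
sbml_gpr <- function(node, id) {
  # fbc-prefixed elements keep their namespace even after stripping the
  # default one, so match on local names
  assoc <- xml2::xml_find_first(
    node, "./*[local-name()='geneProductAssociation']")
  if (!inherits(assoc, "xml_missing")) {
    child <- xml2::xml_find_first(assoc, "./*")
    txt <- fbc_to_string(child)
    if (!nzchar(txt)) return(NULL)
    return(tryCatch(parse_gpr(txt), error = function(e) {
      stop("bad GPR for reaction '", id, "': ", conditionMessage(e),
           call. = FALSE)
    }))
  }
  notes <- xml2::xml_find_first(node, "./notes")
  if (!inherits(notes, "xml_missing")) {
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n<]*", txt))
    if (length(m) == 1) {
      rule <- trimws(sub("GENE_ASSOCIATION:", "", m))
      if (nzchar(rule)) {
        return(tryCatch(parse_gpr(rule), error = function(e) {
          stop("bad GPR for reaction '", id, "': ", conditionMessage(e),
               call. = FALSE)
        }))
      }
    }
  }
  NULL
}

fbc_to_string <- function(node) {
  if (inherits(node, "xml_missing") || is.null(node)) return("")
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    lab <- xml2::xml_attr(node, "label")
    ref <- xml2::xml_attr(node, "geneProduct")
    return(if (!is.na(lab) && nzchar(lab)) lab else ref)
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, fbc_to_string, "")
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return("")
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a model in the package's JSON dialect
#'
#' @param model A [metabolic_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  reactions <- purrr::pmap(model$reactions, function(id, stoich, gpr, reversible) {
    out <- list(id = id, metabolites = as.list(stoich),
                reversible = reversible)
    if (!is.null(gpr)) out$gpr <- gpr_to_string(gpr)
    out
  })
  species <- purrr::pmap(model$species[, c("id", "compartment")],
                         function(id, compartment) {
                           list(id = id, compartment = compartment)
                         })
  jsonlite::write_json(list(reactions = reactions, species = species),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|NA|%` <- function(a, b) {
  a[is.na(a)] <- b
  a
}
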