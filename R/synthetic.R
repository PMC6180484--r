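#' Specification for a synthetic fitness screen fixture
#'
#' The generator emits a toy metabolic model plus matching fitness,
#' insertion, region and expression data with known ground truth, so the
#' whole assignment pipeline can be exercised and validated without any
#' external dataset.
#'
#' The model is built from three-reaction linear pathway motifs
#' `flank_a -> mid -> flank_b` stitched by shared intermediates.  Latent
#' condition profiles are drawn per motif: the two flank latents are
#' independent standard normals and the middle latent is their normalized
#' sum, which makes the middle reaction's planted gene the unique best
#' neighborhood correlate (a flank gene correlates perfectly with its own
#' reaction but only weakly with the opposite flank).  Middle reactions are
#' the adequate ones; a configurable share of them is emitted GPR-less as
#' planted orphans.
#'
#' @param n_reactions Total reactions; must be a positive multiple of 3
#'   (default 60, i.e. 20 motifs).
#' @param n_genes Total genes including decoys (default 80).
#' @param n_conditions Screen conditions (default 48).
#' @param orphan_fraction Fraction of reactions emitted without a GPR;
#'   orphans are taken from motif middles (default 0.1).
#' @param currency_species Number of planted currency metabolites
#'   (default 2).
#' @param currency_multiplicity Reactions each currency metabolite touches
#'   (default 12, just above the pruning cutoff of 11).
#' @param gpr_mix Named fractions `single`, `or`, `and` of GPR rule shapes
#'   for non-orphan reactions; must sum to 1
#'   (default `c(single = 0.8, or = 0.1, and = 0.1)`).
#' @param signal_strength Correlation of a true gene's vector with its
#'   reaction's latent profile, in `[0, 1]` (default 1).
#' @param noise_sd Additional measurement noise s.d. (default 0).
#' @param seed Mandatory integer seed; every emitted object is a
#'   deterministic function of the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_reactions = 60L, n_genes = 80L,
                         n_conditions = 48L, orphan_fraction = 0.1,
                         currency_species = 2L, currency_multiplicity = 12L,
                         gpr_mix = c(single = 0.8, or = 0.1, and = 0.1),
                         signal_strength = 1, noise_sd = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_reactions < 3 || n_reactions %% 3 != 0) {
    stop("n_reactions must be a positive multiple of 3", call. = FALSE)
  }
  if (abs(sum(gpr_mix) - 1) > 1e-8 ||
      !setequal(names(gpr_mix), c("single", "or", "and"))) {
    stop("gpr_mix must be named fractions single/or/and summing to 1",
         call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 1) {
    stop("signal_strength must be in [0,1]", call. = FALSE)
  }
  if (orphan_fraction < 0 || orphan_fraction * n_reactions > n_reactions / 3) {
    stop("orphan_fraction must leave orphans <= number of motif middles",
         call. = FALSE)
  }
  structure(list(
    n_reactions = as.integer(n_reactions), n_genes = as.integer(n_genes),
    n_conditions = as.integer(n_conditions),
    orphan_fraction = orphan_fraction,
    currency_species = as.integer(currency_species),
    currency_multiplicity = as.integer(currency_multiplicity),
    gpr_mix = gpr_mix, signal_strength = signal_strength,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  code
}

#' Generate the toy metabolic model and its ground truth
#'
#' @param spec A [fixture_spec].
#' @return List with `model` (a [metabolic_model]) and `truth`, a list
#'   holding `assignments` (tibble `gene`, `reaction`, `role`), planted
#'   `orphans`, the planted `adequate` reaction set (motif middles),
#'   `currency` species ids and the `motif` map.
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    n_motifs <- spec$n_reactions %/% 3L
    n_orphans <- round(spec$orphan_fraction * spec$n_reactions)
    if (n_orphans > n_motifs) stop("too many orphans for motif count",
                                   call. = FALSE)
    rx_id <- function(m, part) sprintf("R%02d%s", m, part)
    motifs <- tibble::tibble(
      motif = seq_len(n_motifs),
      flank_a = rx_id(seq_len(n_motifs), "a"),
      mid = rx_id(seq_len(n_motifs), "m"),
      flank_b = rx_id(seq_len(n_motifs), "b")
    )
    orphan_mids <- if (n_orphans > 0) {
      motifs$mid[sample(n_motifs, n_orphans)]
    } else character()

    # chain S{m}0 ->a S{m}1 ->mid S{m}2 ->b S{m}3
    sp <- function(m, i) sprintf("S%02d_%d", m, i)
    reactions <- purrr::pmap_dfr(motifs, function(motif, flank_a, mid, flank_b) {
      tibble::tibble(
        id = c(flank_a, mid, flank_b),
        stoich = list(
          stats::setNames(c(-1, 1), c(sp(motif, 0), sp(motif, 1))),
          stats::setNames(c(-1, 1), c(sp(motif, 1), sp(motif, 2))),
          stats::setNames(c(-1, 1), c(sp(motif, 2), sp(motif, 3)))
        ),
        reversible = FALSE
      )
    })

    # currency metabolites ride along in middle reactions of distinct motifs
    currency <- character()
    if (spec$currency_species > 0) {
      if (spec$currency_multiplicity > n_motifs) {
        stop("currency_multiplicity exceeds motif count", call. = FALSE)
      }
      for (ci in seq_len(spec$currency_species)) {
        cid <- sprintf("CUR%02d", ci)
        currency <- c(currency, cid)
        hosts <- motifs$mid[((ci - 1 + seq_len(spec$currency_multiplicity) - 1)
                             %% n_motifs) + 1]
        hosts <- unique(hosts)
        for (h in hosts) {
          k <- which(reactions$id == h)
          reactions$stoich[[k]] <- c(reactions$stoich[[k]],
                                     stats::setNames(-1, cid))
        }
      }
    }

    # gene assignment: every reaction gets planted gene(s); orphans keep
    # theirs only in the truth table
    shapes <- sample(names(spec$gpr_mix), spec$n_reactions, replace = TRUE,
                     prob = spec$gpr_mix)
    gene_counter <- 0L
    next_gene <- function() {
      gene_counter <<- gene_counter + 1L
      sprintf("g%03d", gene_counter)
    }
    assignments <- list()
    gprs <- vector("list", spec$n_reactions)
    for (k in seq_len(spec$n_reactions)) {
      rid <- reactions$id[k]
      shape <- if (rid %in% orphan_mids) "single" else shapes[k]
      genes_k <- if (shape == "single") next_gene() else c(next_gene(), next_gene())
      assignments[[k]] <- tibble::tibble(gene = genes_k, reaction = rid,
                                         role = "true")
      if (!rid %in% orphan_mids) {
        gprs[[k]] <- switch(shape,
          single = gpr(list(genes_k)),
          or = gpr(list(genes_k[1], genes_k[2])),
          and = gpr(list(genes_k))
        )
      }
    }
    assignments <- dplyr::bind_rows(assignments)
    if (gene_counter > spec$n_genes) {
      stop("gpr_mix demands more genes than n_genes; raise n_genes",
           call. = FALSE)
    }
    decoys <- if (gene_counter < spec$n_genes) {
      vapply(seq_len(spec$n_genes - gene_counter), function(i) next_gene(), "")
    } else character()

    reactions$gpr <- gprs
    model <- metabolic_model(reactions)
    truth <- list(
      assignments = assignments,
      decoys = decoys,
      orphans = orphan_mids,
      adequate = motifs$mid,
      currency = currency,
      motifs = motifs
    )
    list(model = model, truth = truth)
  })
}

# latent condition profiles per reaction: flank latents iid N(0,1),
# middle latent = (a+b)/sqrt(2)
motif_latents <- function(truth, n_cond) {
  lat <- list()
  for (i in seq_len(nrow(truth$motifs))) {
    a <- stats::rnorm(n_cond)
    b <- stats::rnorm(n_cond)
    lat[[truth$motifs$flank_a[i]]] <- a
    lat[[truth$motifs$flank_b[i]]] <- b
    lat[[truth$motifs$mid[i]]] <- (a + b) / sqrt(2)
  }
  lat
}

gene_vectors_from_latents <- function(truth, latents, n_cond, s, noise_sd) {
  all_genes <- c(truth$assignments$gene, truth$decoys)
  vals <- matrix(NA_real_, length(all_genes), n_cond,
                 dimnames = list(all_genes, sprintf("c%02d", seq_len(n_cond))))
  for (i in seq_len(nrow(truth$assignments))) {
    g <- truth$assignments$gene[i]
    r <- truth$assignments$reaction[i]
    vals[g, ] <- s * latents[[r]] + sqrt(1 - s^2) * stats::rnorm(n_cond) +
      noise_sd * stats::rnorm(n_cond)
  }
  for (g in truth$decoys) {
    vals[g, ] <- stats::rnorm(n_cond) + noise_sd * stats::rnorm(n_cond)
  }
  vals
}

#' Simulate the gene fitness screen for a toy model
#'
#' Each true gene's fitness vector is its reaction's latent profile scaled
#' by `signal_strength` plus independent noise; decoy genes are pure noise.
#' Also emits a per-insertion table (insertions scattered in each gene's
#' promoter and CDS inherit the gene's scores plus noise) and the matching
#' region annotation with random promoter sequences.
#'
#' @param model,truth From [make_toy_model()].
#' @param spec The same [fixture_spec].
#' @return List with `gene_matrix` (raw [profile_matrix]), `insertions`
#'   (tibble) and `regions` (tibble as in [read_region_tsv()]).
#' @export
simulate_fitness <- function(model, truth, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 1L, {
    latents <- motif_latents(truth, spec$n_conditions)
    vals <- gene_vectors_from_latents(truth, latents, spec$n_conditions,
                                      spec$signal_strength, spec$noise_sd)
    gene_matrix <- profile_matrix(vals)

    genes <- rownames(vals)
    gene_start <- 1000L * seq_along(genes)
    regions <- dplyr::bind_rows(
      tibble::tibble(
        scaffold = "chr", start = gene_start - 100L, end = gene_start,
        id = paste0("prom_", genes), kind = "promoter", strand = "+",
        gene = genes, sigma = sample(c("sigma70", "sigma28"), length(genes),
                                     replace = TRUE, prob = c(0.8, 0.2)),
        sequence = vapply(genes, function(g) {
          paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                collapse = "")
        }, "", USE.NAMES = FALSE)
      ),
      tibble::tibble(
        scaffold = "chr", start = gene_start, end = gene_start + 600L,
        id = paste0("cds_", genes), kind = "cds", strand = "+",
        gene = genes, sigma = NA_character_, sequence = NA_character_
      )
    )
    ins_per_region <- 3L
    insertions <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      r <- regions[i, ]
      pos <- sort(sample(seq(r$start, r$end - 1L), ins_per_region))
      sc <- vals[r$gene, , drop = FALSE]
      out <- tibble::tibble(position = pos, scaffold = r$scaffold)
      noise <- matrix(stats::rnorm(ins_per_region * ncol(sc), sd = 0.2),
                      ins_per_region)
      scores <- matrix(rep(sc, each = ins_per_region), ins_per_region) + noise
      colnames(scores) <- colnames(sc)
      dplyr::bind_cols(out, tibble::as_tibble(scores))
    })
    list(gene_matrix = gene_matrix, insertions = insertions,
         regions = regions)
  })
}

#' Simulate companion expression datasets
#'
#' Each dataset draws its own latent profiles over its samples but keeps
#' the same gene-to-reaction association structure, with `shared_strength`
#' playing the role `signal_strength` plays for fitness; at
#' `shared_strength = 0` expression carries no assignment signal.
#'
#' @param model,truth From [make_toy_model()].
#' @param spec The same [fixture_spec].
#' @param n_samples Integer vector of dataset sizes (default `c(11, 36)`,
#'   one microarray-scale and one RNA-seq-scale dataset).
#' @param shared_strength Gene-to-latent correlation per dataset
#'   (default `spec$signal_strength`).
#' @return Named list of raw gene [profile_matrix] objects
#'   (`expr1`, `expr2`, ...).
#' @export
simulate_expression <- function(model, truth, spec, n_samples = c(11L, 36L),
                                shared_strength = spec$signal_strength) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- list()
  for (d in seq_along(n_samples)) {
    out[[paste0("expr", d)]] <- with_seed(spec$seed + 1000L + d, {
      latents <- motif_latents(truth, n_samples[d])
      vals <- gene_vectors_from_latents(truth, latents, n_samples[d],
                                        shared_strength, spec$noise_sd)
      colnames(vals) <- sprintf("s%02d", seq_len(n_samples[d]))
      profile_matrix(vals)
    })
  }
  out
}

#' Write a full synthetic screen to disk
#'
#' Emits the model (JSON dialect), gene fitness TSV, insertion TSV, region
#' TSV, expression TSVs and a truth JSON into a directory; every file
#' round-trips through the package's readers.
#'
#' @param spec A [fixture_spec].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_screen <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- make_toy_model(spec)
  fit <- simulate_fitness(tm$model, tm$truth, spec)
  expr <- simulate_expression(tm$model, tm$truth, spec)
  paths <- list(
    model = file.path(dir, "model.json"),
    fitness = file.path(dir, "fitness.tsv"),
    insertions = file.path(dir, "insertions.tsv"),
    regions = file.path(dir, "regions.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_model_json(tm$model, paths$model)
  write_profile_tsv(fit$gene_matrix, paths$fitness, id_col = "gene")
  readr::write_tsv(fit$insertions, paths$insertions, progress = FALSE)
  readr::write_tsv(fit$regions, paths$regions, progress = FALSE)
  for (ds in names(expr)) {
    paths[[ds]] <- file.path(dir, paste0(ds, ".tsv"))
    write_profile_tsv(expr[[ds]], paths[[ds]], id_col = "gene")
  }
  jsonlite::write_json(
    list(assignments = tm$truth$assignments, decoys = tm$truth$decoys,
         orphans = tm$truth$orphans, adequate = tm$truth$adequate,
         currency = tm$truth$currency),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}
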