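#' Configuration for the synthetic DGE study generator
#'
#' Defines the conditions a simulated three-species tag-profiling study is
#' generated under: transcriptome size and divergence, library depth,
#' planted differential expression, and singleton sequencing-error noise.
#'
#' @param n_genes Number of orthologous genes (one transcript per species).
#' @param gene_length Min/max transcript length in nt; lengths are drawn
#'   uniformly.
#' @param species Species labels; the first is also the primary reference
#'   database of the mapping order.
#' @param divergence Per-site substitution probability applied
#'   independently to each species' copy of the ancestral sequence
#'   (in `[0, 0.3]`). A 21-nt tag window survives intact in one species
#'   with probability `(1 - divergence)^21`, and is shared by all three
#'   species with probability `(1 - divergence)^63`.
#' @param library_depth Target raw tags per library.
#' @param de_fraction Fraction of genes with a planted expression effect.
#' @param effect_log2 Magnitude of planted log2 fold changes.
#' @param singleton_noise_rate Fraction of raw library mass emitted as
#'   unique random error tags of copy number 1 (removed by cleaning).
#' @param expression_sdlog Standard deviation (log scale) of the lognormal
#'   baseline expression distribution shared by all species.
#' @param seed Integer seed; the same configuration and seed reproduce
#'   byte-identical outputs.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             gene_length = c(400, 1200),
                             species = c("MED", "MEAM1", "AsiaII3"),
                             divergence = 0.01,
                             library_depth = 1e6,
                             de_fraction = 0.15,
                             effect_log2 = 2,
                             singleton_noise_rate = 0.03,
                             expression_sdlog = 1.5,
                             seed = 1L) {
  stopifnot(n_genes >= 1, length(gene_length) == 2L,
            gene_length[1] >= 25, gene_length[1] <= gene_length[2],
            length(species) >= 2L, !anyDuplicated(species),
            divergence >= 0, divergence <= 0.3,
            library_depth > 0,
            de_fraction >= 0, de_fraction <= 1,
            effect_log2 >= 0,
             singleton_noise_rate >= 0, singleton_noise_rate < 1,
            expression_sdlog > 0)
  structure(
    list(n_genes = as.integer(n_genes), gene_length = as.integer(gene_length),
         species = species, divergence = divergence,
         library_depth = library_depth, de_fraction = de_fraction,
         effect_log2 = effect_log2,
         singleton_noise_rate = singleton_noise_rate,
         expression_sdlog = expression_sdlog, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

BASES <- c("A", "C", "G", "T")

# gene ids g0001, g0002, ...
gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Simulate divergent transcriptomes with known orthology
#'
#' Draws one ancestral transcript per gene (uniform random sequence with
#' one guaranteed internal `CATG` site so every gene is taggable), then
#' derives each species' copy by independent per-site substitution at the
#' configured divergence. Substitutions falling inside tag windows destroy
#' (or occasionally create) tags naturally, so at positive divergence some
#' genes lose cross-species common tags and some tags survive only in a
#' subset of species — exercising the fallback mapping downstream.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `transcriptomes` (named list per species: named
#'   character vector of sequences, ids `<species>|<gene>`), `orthology`
#'   (data.frame `gene_id` plus one transcript-id column per species), and
#'   `ancestors` (named character vector of the ancestral sequences, for
#'   tag-survival diagnostics).
#' @export
simulate_transcriptomes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  ids <- gene_ids(n)
  lens <- sample(cfg$gene_length[1]:cfg$gene_length[2], n, replace = TRUE)
  ancestors <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample(BASES, lens[i], replace = TRUE)
    pos <- sample.int(lens[i] - 24L, 1L)    # CATG + 17 nt fit after pos
    s[pos:(pos + 3L)] <- c("C", "A", "T", "G")
    ancestors[[i]] <- s
  }
  tx <- vector("list", length(cfg$species))
  names(tx) <- cfg$species
  for (sp in cfg$species) {
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- ancestors[[i]]
      if (cfg$divergence > 0) {
        mut <- which(stats::runif(length(s)) < cfg$divergence)
        if (length(mut)) {
          # substitute with one of the three other bases
          repl <- vapply(s[mut],
                         function(b) sample(setdiff(BASES, b), 1L), "")
          s[mut] <- repl
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- paste(sp, ids, sep = "|")
    tx[[sp]] <- seqs
  }
  orthology <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (sp in cfg$species) orthology[[sp]] <- paste(sp, ids, sep = "|")
  anc <- vapply(ancestors, paste, "", collapse = "")
  names(anc) <- ids
  common_frac <- NA_real_
  if (cfg$divergence > 0) {
    shared <- vapply(seq_len(n), function(i) {
      w <- extract_tags(anc[[i]])
      length(w) > 0 && any(vapply(w, function(t) {
        all(vapply(cfg$species, function(sp) grepl(t, tx[[sp]][i], fixed = TRUE),
                   TRUE))
      }, TRUE))
    }, TRUE)
    common_frac <- mean(shared)
    if (common_frac == 0) {
      warning("no gene retains a cross-species common tag at divergence ",
              cfg$divergence, "; downstream mapping will be empty")
    }
  }
  list(transcriptomes = tx, orthology = orthology, ancestors = anc,
       common_tag_gene_fraction = common_frac)
}

#' Ground-truth expression table with planted effects
#'
#' Baseline expression is lognormal and shared by all species; each
#' planted DE gene has one randomly chosen species whose expression is
#' multiplied by `2^(+-effect_log2)` (random sign). Per-species true TPM
#' vectors are renormalised to sum to one million.
#'
#' @param cfg A [synthetic_config()].
#' @return data.frame of class `truth_table`: `gene_id`, `is_de`,
#'   `de_species` (`NA` for null genes), `de_sign` (+1/-1/`NA`), and one
#'   `tpm.<species>` column per species.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  base <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$expression_sdlog)
  n_de <- round(cfg$de_fraction * n)
  de_idx <- sort(sample.int(n, n_de))
  de_species <- rep(NA_character_, n)
  de_sign <- rep(NA_integer_, n)
  if (n_de > 0) {
    de_species[de_idx] <- sample(cfg$species, n_de, replace = TRUE)
    de_sign[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  }
  out <- data.frame(gene_id = gene_ids(n),
                    is_de = seq_len(n) %in% de_idx,
                    de_species = de_species, de_sign = de_sign,
                    stringsAsFactors = FALSE)
  for (sp in cfg$species) {
    expr <- base
    hit <- !is.na(de_species) & de_species == sp
    expr[hit] <- expr[hit] * 2^(de_sign[hit] * cfg$effect_log2)
    out[[paste0("tpm.", sp)]] <- expr / sum(expr) * 1e6
  }
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Planted log2 effect of each gene for one species pair
#'
#' The log2 ratio of true TPM (`species_b` over `species_a`), i.e. the
#' effect the DE stage should estimate. A gene is truly DE for the pair
#' when its planted effect involves one of the two species.
#'
#' @param truth A [simulate_truth()] table.
#' @param species_a,species_b Species labels.
#' @return data.frame `gene_id`, `true_log2`, `is_de_pair`.
#' @export
truth_effects <- function(truth, species_a, species_b) {
  stopifnot(inherits(truth, "truth_table"))
  ta <- truth[[paste0("tpm.", species_a)]]
  tb <- truth[[paste0("tpm.", species_b)]]
  data.frame(
    gene_id = truth$gene_id,
    true_log2 = log2(tb / ta),
    is_de_pair = truth$is_de & truth$de_species %in% c(species_a, species_b),
    stringsAsFactors = FALSE
  )
}

#' Sample raw tag libraries from transcriptomes and true expression
#'
#' Per species, `library_depth * (1 - singleton_noise_rate)` tags are drawn
#' multinomially: gene proportional to its true TPM, then tag uniformly
#' among the gene's extractable `CATG`+17 tags in that species (a gene
#' whose transcript has lost all tag sites emits nothing). Singleton noise
#' is injected as `library_depth * singleton_noise_rate` unique random
#' `CATG`-anchored 21-mers of copy number 1, mimicking sequencing-error
#' tags that cleaning removes.
#'
#' @param sim Result of [simulate_transcriptomes()].
#' @param truth Result of [simulate_truth()] (same config).
#' @param cfg The shared [synthetic_config()].
#' @return Named list of raw [tag_library] objects, one per species.
#' @export
simulate_tag_libraries <- function(sim, truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "truth_table"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_genes
  depth_genes <- round(cfg$library_depth * (1 - cfg$singleton_noise_rate))
  n_noise <- round(cfg$library_depth * cfg$singleton_noise_rate)
  libs <- vector("list", length(cfg$species))
  names(libs) <- cfg$species
  for (sp in cfg$species) {
    seqs <- sim$transcriptomes[[sp]]
    gene_tags <- lapply(seqs, extract_tags)
    tpm_true <- truth[[paste0("tpm.", sp)]]
    gcount <- as.vector(stats::rmultinom(1L, depth_genes, tpm_true))
    tag_acc <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      if (gcount[i] == 0L) next
      tg <- gene_tags[[i]]
      k <- length(tg)
      if (k == 0L) next                      # gene lost every tag site
      tc <- if (k == 1L) gcount[i] else
        as.vector(stats::rmultinom(1L, gcount[i], rep(1 / k, k)))
      for (j in seq_len(k)) {
        if (tc[j] == 0L) next
        prev <- tag_acc[[tg[j]]]
        tag_acc[[tg[j]]] <- if (is.null(prev)) tc[j] else prev + tc[j]
      }
    }
    tags <- ls(tag_acc, sorted = TRUE)
    counts <- vapply(tags, function(t) tag_acc[[t]], 0)
    if (n_noise > 0L) {
      noise <- unique(random_tags(ceiling(n_noise * 1.05)))
      noise <- setdiff(noise, tags)[seq_len(min(n_noise, length(noise)))]
      tags <- c(tags, noise)
      counts <- c(counts, rep(1, length(noise)))
    }
    libs[[sp]] <- tag_library(tags, counts, sp)
  }
  libs
}

# random CATG-anchored 21-mers
random_tags <- function(k) {
  suffix <- matrix(sample(BASES, 17L * k, replace = TRUE), nrow = k)
  paste0("CATG", apply(suffix, 1L, paste, collapse = ""))
}

#' Random term-annotation map over synthetic genes
#'
#' Groups genes into terms of random sizes (default 3-80 genes, so some
#' terms fall below the enrichment size filter), optionally planting terms
#' deliberately packed with DE genes to give enrichment something to find.
#' Each term lists every species' transcript identifier for its member
#' genes (`<species>|<gene>`), mirroring annotation databases keyed by the
#' reference assemblies, so the map matches ortholog tables whichever
#' database a gene was assigned from.
#'
#' @param truth A [simulate_truth()] table.
#' @param cfg The shared [synthetic_config()] (its seed stream is used).
#' @param n_terms Number of random terms.
#' @param size_range Min/max genes per term.
#' @param n_enriched_terms Number of planted terms whose genes are drawn
#'   preferentially (90 percent) from the DE genes.
#' @param category Category label for all generated terms.
#' @return An [annotation_map()].
#' @export
simulate_annotation <- function(truth, cfg, n_terms = 50,
                                size_range = c(3, 80),
                                n_enriched_terms = 2,
                                category = "KEGG") {
  stopifnot(inherits(truth, "truth_table"))
  set.seed(cfg$seed + 3L)
  genes <- truth$gene_id
  de <- truth$gene_id[truth$is_de]
  terms <- list()
  for (i in seq_len(n_terms)) {
    sz <- sample(size_range[1]:size_range[2], 1L)
    terms[[sprintf("TERM%03d", i)]] <- sample(genes, min(sz, length(genes)))
  }
  if (n_enriched_terms > 0 && length(de) >= 5) {
    for (i in seq_len(n_enriched_terms)) {
      sz <- min(length(de), sample(10:30, 1L))
      n_de_part <- round(0.9 * sz)
      part <- c(sample(de, n_de_part),
                sample(setdiff(genes, de), sz - n_de_part))
      terms[[sprintf("DETERM%02d", i)]] <- part
    }
  }
  # expand gene ids to all species-qualified transcript ids
  terms <- lapply(terms, function(g) {
    as.vector(vapply(cfg$species, function(sp) paste(sp, g, sep = "|"),
                     character(length(g))))
  })
  annotation_map(terms,
                 description = stats::setNames(
                   paste("synthetic term", names(terms)), names(terms)),
                 category = stats::setNames(
                   rep(category, length(terms)), names(terms)))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing everything one pipeline run consumes:
#' transcriptomes, orthology map, truth table, raw tag libraries and an
#' annotation map, all from one configuration and seed.
#'
#' @param cfg A [synthetic_config()].
#' @param annotation Generate an annotation map too? Default `TRUE`.
#' @return List with `config`, `transcriptomes`, `orthology`, `truth`,
#'   `libraries` and (optionally) `annotation`.
#' @export
simulate_study <- function(cfg = synthetic_config(), annotation = TRUE) {
  sim <- simulate_transcriptomes(cfg)
  truth <- simulate_truth(cfg)
  libs <- simulate_tag_libraries(sim, truth, cfg)
  out <- list(config = cfg, transcriptomes = sim$transcriptomes,
              orthology = sim$orthology, truth = truth, libraries = libs)
  if (annotation) out$annotation <- simulate_annotation(truth, cfg)
  out
}
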