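#' Pipeline configuration
#'
#' Bundles the thresholds and options of a full cross-species DGE run.
#'
#' @param db_order Ordered reference-database labels for the sequential
#'   ortholog mapping (a permutation of the species labels).
#' @param fdr_threshold Strict FDR cutoff for DEG calling (default 0.001).
#' @param lfc_threshold Inclusive |log2 ratio| cutoff (default 1).
#' @param alpha Inclusive enrichment significance level (default 0.05).
#' @param min_term_size Minimum universe genes per tested term (default 5).
#' @param pseudocount Pseudocount for log2 ratios (default 1).
#' @param ambiguity Ambiguous-tag policy for [assign_orthologs()].
#' @param seed Seed recorded into output headers (the pipeline itself is
#'   deterministic; the seed documents how its inputs were generated).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(db_order,
                            fdr_threshold = 0.001,
                            lfc_threshold = 1,
                            alpha = 0.05,
                            min_term_size = 5,
                            pseudocount = 1,
                            ambiguity = c("per_db", "joint"),
                            seed = NA_integer_) {
  stopifnot(fdr_threshold > 0, lfc_threshold > 0, alpha > 0,
            min_term_size >= 1, pseudocount >= 0)
  structure(
    list(db_order = db_order, fdr_threshold = fdr_threshold,
         lfc_threshold = lfc_threshold, alpha = alpha,
         min_term_size = min_term_size, pseudocount = pseudocount,
         ambiguity = match.arg(ambiguity), seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full cross-species DGE tag pipeline
#'
#' Orchestrates every stage on in-memory objects: clean the raw libraries,
#' intersect their distinct tags, assign orthologous genes against the
#' reference indexes in the configured priority order, aggregate per-gene
#' counts and TPM, call DEGs for every pairwise species comparison, and
#' (when an annotation map is supplied) score term enrichment of each
#' comparison's DEG set.
#'
#' @param indexes Named list of [build_tag_index()] objects, one per
#'   species (all species in `config$db_order` must be present).
#' @param libraries Named list of raw [tag_library] objects, one per
#'   species.
#' @param config A [pipeline_config()]; defaults to one whose `db_order`
#'   is the order of `indexes`.
#' @param annotation Optional [annotation_map()] for enrichment.
#' @return Object of class `dge_pipeline`: list with `config`,
#'   `libraries` (cleaned), `library_stats` (per-species raw/clean/common
#'   totals and distinct counts), `common` (tag vector), `orthologs`
#'   (filled `ortholog_table`), `deg` (named list of `deg_table`, one per
#'   pairwise comparison `"A_vs_B"`), `deg_summary` (up/down/total per
#'   comparison) and `enrichment` (named list of `enrichment_table` or
#'   `NULL`).
#' @export
run_pipeline <- function(indexes, libraries, config = NULL,
                         annotation = NULL) {
  if (is.null(names(indexes)) || is.null(names(libraries))) {
    stop("'indexes' and 'libraries' must be named by species")
  }
  if (is.null(config)) config <- pipeline_config(db_order = names(indexes))
  stopifnot(inherits(config, "pipeline_config"))
  species <- config$db_order
  if (!all(species %in% names(indexes))) {
    stop("stage build-index: missing index for ",
         paste(setdiff(species, names(indexes)), collapse = ", "))
  }
  if (!all(species %in% names(libraries))) {
    stop("stage clean: missing library for ",
         paste(setdiff(species, names(libraries)), collapse = ", "))
  }
  raw <- libraries[species]
  clean <- lapply(raw, clean_tags)

  common <- common_tags(clean)
  table <- assign_orthologs(common, indexes[species],
                            ambiguity = config$ambiguity)
  table <- gene_counts(table, clean)

  stats <- data.frame(
    species = species,
    raw_total = vapply(raw, `[[`, 0, "total"),
    raw_distinct = vapply(raw, `[[`, 0, "distinct"),
    clean_total = vapply(clean, `[[`, 0, "total"),
    clean_distinct = vapply(clean, `[[`, 0, "distinct"),
    common_total = vapply(clean, function(l) sum(as.numeric(l$counts[common])),
                          0),
    common_distinct = length(common),
    stringsAsFactors = FALSE, row.names = NULL
  )

  pairs <- utils::combn(species, 2L, simplify = FALSE)
  deg <- list()
  for (pr in pairs) {
    nm <- paste(pr[1L], "vs", pr[2L], sep = "_")
    deg[[nm]] <- call_degs(table, pr[1L], pr[2L],
                           fdr_threshold = config$fdr_threshold,
                           lfc_threshold = config$lfc_threshold,
                           pseudocount = config$pseudocount)
  }
  deg_summary <- data.frame(
    comparison = names(deg),
    up = vapply(deg, function(d) sum(d$status == "up"), 0L),
    down = vapply(deg, function(d) sum(d$status == "down"), 0L),
    total = vapply(deg, function(d) sum(d$status != "ns"), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )

  enr <- NULL
  if (!is.null(annotation)) {
    universe <- table$genes$gene_id
    enr <- lapply(deg, function(d) {
      enrich(d$gene_id[d$status != "ns"], annotation, universe,
             min_term_size = config$min_term_size, alpha = config$alpha,
             warn_unknown = FALSE)
    })
  }

  structure(
    list(config = config, libraries = clean, library_stats = stats,
         common = common, orthologs = table, deg = deg,
         deg_summary = deg_summary, enrichment = enr),
    class = "dge_pipeline"
  )
}

#' @export
print.dge_pipeline <- function(x, ...) {
  cat("Cross-species DGE tag pipeline run\n")
  cat("  database order: ", paste(x$config$db_order, collapse = " > "),
      "\n", sep = "")
  cat("  common distinct tags: ", length(x$common), "\n", sep = "")
  cat("  orthologous genes: ", nrow(x$orthologs$genes), "\n", sep = "")
  cat("  DEGs (FDR<", x$config$fdr_threshold, ", |log2|>=",
      x$config$lfc_threshold, "):\n", sep = "")
  for (i in seq_len(nrow(x$deg_summary))) {
    with(x$deg_summary[i, ],
         cat("    ", comparison, ": ", total, " (", up, " up, ",
             down, " down)\n", sep = ""))
  }
  invisible(x)
}

#' @export
summary.dge_pipeline <- function(object, ...) {
  out <- list(library_stats = object$library_stats,
              deg_summary = object$deg_summary,
              n_orthologs = nrow(object$orthologs$genes),
              n_common = length(object$common),
              n_ambiguous = length(object$orthologs$ambiguous_tags),
              n_unmatched = length(object$orthologs$unmatched_tags))
  class(out) <- "summary.dge_pipeline"
  out
}

#' @export
print.summary.dge_pipeline <- function(x, ...) {
  cat("Library statistics:\n")
  print(x$library_stats, row.names = FALSE)
  cat("\nCommon tags: ", x$n_common,
      " (", x$n_ambiguous, " ambiguous, ", x$n_unmatched,
      " unmatched; ", x$n_orthologs, " orthologous genes)\n", sep = "")
  cat("\nDifferential expression:\n")
  print(x$deg_summary, row.names = FALSE)
  invisible(x)
}

#' Plot a pipeline run
#'
#' Barplot of the per-species distribution of ortholog expression levels
#' over low/mid/high TPM categories.
#'
#' @param x A `dge_pipeline` result.
#' @param edges TPM category boundaries, see [bin_expression()].
#' @param ... Passed to [graphics::barplot()].
#' @return The plotted proportion matrix, invisibly.
#' @export
plot.dge_pipeline <- function(x, edges = c(5, 50), ...) {
  tpm <- x$orthologs$tpm
  prop <- sapply(colnames(tpm), function(s) {
    tab <- table(bin_expression(tpm[, s], edges))
    as.vector(tab) / sum(tab)
  })
  rownames(prop) <- levels(bin_expression(0, edges))
  graphics::barplot(prop * 100, beside = TRUE,
                    legend.text = rownames(prop),
                    ylab = "% of orthologous genes",
                    xlab = "species", ...)
  invisible(prop)
}

#' Write every pipeline output table to a directory
#'
#' Emits the ortholog table, one DEG table per comparison, enrichment
#' tables (when computed) and a library-statistics summary, each as TSV
#' with a header recording the package version, a configuration hash and
#' the recorded seed. A machine-readable `summary.json`-style TSV of the
#' DEG tallies is included.
#'
#' @param result A `dge_pipeline` result.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "dge_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(
    paste0("tagdge version ", as.character(utils::packageVersion("tagdge"))),
    paste0("config ", config_hash(result$config)),
    paste0("seed ", result$config$seed)
  )
  paths <- character(0)
  p <- file.path(dir, "library_stats.tsv")
  con <- file(p, "w"); writeLines(paste0("# ", hdr), con)
  utils::write.table(result$library_stats, con, sep = "\t", quote = FALSE,
                     row.names = FALSE); close(con)
  paths <- c(paths, p)
  p <- file.path(dir, "orthologs.tsv")
  write_ortholog_table(result$orthologs, p, header_comment = hdr)
  paths <- c(paths, p)
  for (nm in names(result$deg)) {
    p <- file.path(dir, paste0("deg_", nm, ".tsv"))
    write_deg_table(result$deg[[nm]], p, header_comment = hdr)
    paths <- c(paths, p)
  }
  if (!is.null(result$enrichment)) {
    for (nm in names(result$enrichment)) {
      p <- file.path(dir, paste0("enrichment_", nm, ".tsv"))
      write_enrichment_table(result$enrichment[[nm]], p, header_comment = hdr)
      paths <- c(paths, p)
    }
  }
  p <- file.path(dir, "deg_summary.tsv")
  con <- file(p, "w"); writeLines(paste0("# ", hdr), con)
  utils::write.table(result$deg_summary, con, sep = "\t", quote = FALSE,
                     row.names = FALSE); close(con)
  paths <- c(paths, p)
  invisible(paths)
}

# md5 of the deparsed configuration (stable across sessions)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}
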