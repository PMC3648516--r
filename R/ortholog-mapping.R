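#' Tags shared by every library
#'
#' The exact intersection of the distinct (cleaned) tag sets of two or more
#' libraries. A tag present in every species' library is evidence of an
#' orthologous transcript conserved across the species.
#'
#' @param libs A list of two or more cleaned [tag_library] objects.
#' @return Sorted character vector of common tags.
#' @export
common_tags <- function(libs) {
  if (!is.list(libs) || length(libs) < 2L) {
    stop("at least two tag libraries are required")
  }
  for (l in libs) stopifnot(inherits(l, "tag_library"))
  sets <- lapply(libs, function(l) names(l$counts))
  sort(Reduce(intersect, sets))
}

#' Assign orthologous genes by sequential no-mismatch tag mapping
#'
#' Resolves each common tag against an ordered list of species tag-reference
#' indexes: the tag is looked up in the first database of the order that
#' contains it. A unique hit assigns the tag to that transcript (gene); a
#' multi-transcript hit makes the tag ambiguous and it is discarded; a tag
#' absent from every database is unmatched. Later databases act as a
#' fallback for tags the earlier (possibly incomplete) assemblies lack.
#' Tags resolving to the same transcript are merged into one gene record.
#'
#' @param common Character vector of common tags (from [common_tags()]).
#' @param indexes List of [build_tag_index()] results, ordered by priority
#'   (the first is the primary reference). Species labels must be unique.
#' @param ambiguity `"per_db"` (default) judges ambiguity in the first
#'   database containing the tag; `"joint"` discards a tag that hits
#'   multiple transcripts in *any* database before assignment.
#' @return An object of class `ortholog_table`: list with
#'   \describe{
#'     \item{genes}{data.frame with `gene_id`, `source_db`, `n_tags` and a
#'       list-column `tags` of member 21-mers.}
#'     \item{ambiguous_tags, unmatched_tags}{character vectors.}
#'     \item{db_order}{the priority order of database labels.}
#'     \item{counts, tpm, lib_totals}{filled by [gene_counts()].}
#'   }
#'   The member tags of all genes, the ambiguous tags and the unmatched
#'   tags partition `common`.
#' @export
assign_orthologs <- function(common, indexes,
                             ambiguity = c("per_db", "joint")) {
  ambiguity <- match.arg(ambiguity)
  if (!is.list(indexes) || length(indexes) == 0L) {
    stop("at least one tag reference index is required")
  }
  for (ix in indexes) stopifnot(inherits(ix, "tag_index"))
  db_order <- vapply(indexes, `[[`, "", "species_label")
  if (anyDuplicated(db_order)) stop("duplicate database labels")
  common <- unique(common)

  assigned_tag <- character(0)
  assigned_gene <- character(0)
  assigned_db <- character(0)
  ambiguous <- character(0)

  if (ambiguity == "joint") {
    multi <- lapply(indexes, function(ix) {
      hits <- ix$index[common]
      common[!vapply(hits, is.null, TRUE) & lengths(hits) > 1L]
    })
    ambiguous <- sort(unique(unlist(multi)))
    common <- setdiff(common, ambiguous)
  }

  remaining <- common
  for (k in seq_along(indexes)) {
    if (!length(remaining)) break
    hits <- indexes[[k]]$index[remaining]
    present <- !vapply(hits, is.null, TRUE)
    nh <- lengths(hits)
    uniq <- present & nh == 1L
    multi <- present & nh > 1L
    assigned_tag <- c(assigned_tag, remaining[uniq])
    assigned_gene <- c(assigned_gene, unlist(hits[uniq], use.names = FALSE))
    assigned_db <- c(assigned_db, rep.int(db_order[k], sum(uniq)))
    ambiguous <- c(ambiguous, remaining[multi])
    remaining <- remaining[!present]
  }
  unmatched <- remaining

  if (length(assigned_tag)) {
    key <- paste(assigned_db, assigned_gene, sep = "\r")
    sp <- split(assigned_tag, key)
    ord <- order(names(sp))
    sp <- sp[ord]
    meta <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
    genes <- data.frame(
      gene_id = meta[, 2L],
      source_db = meta[, 1L],
      n_tags = lengths(sp),
      stringsAsFactors = FALSE
    )
    genes$tags <- lapply(sp, sort)
    if (anyDuplicated(genes$gene_id)) {
      stop("gene identifier(s) shared between reference databases: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "))
    }
    ord2 <- order(match(genes$source_db, db_order), genes$gene_id)
    genes <- genes[ord2, , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(0), source_db = character(0),
                        n_tags = integer(0), stringsAsFactors = FALSE)
    genes$tags <- list()
  }

  structure(
    list(genes = genes,
         ambiguous_tags = sort(unique(ambiguous)),
         unmatched_tags = sort(unmatched),
         db_order = db_order,
         counts = NULL, tpm = NULL, lib_totals = NULL),
    class = "ortholog_table"
  )
}

#' Aggregate per-gene tag counts and TPM across species
#'
#' Sums, for every ortholog gene and every species, the library counts of
#' the gene's member tags (every member tag is a common tag, so present in
#' every library), and normalises to tags per million of that library's
#' clean-tag total.
#'
#' @param table An `ortholog_table` from [assign_orthologs()].
#' @param libs Named list of cleaned [tag_library] objects, one per species.
#' @return The table with `counts` and `tpm` matrices (genes x species)
#'   and `lib_totals` filled in.
#' @export
gene_counts <- function(table, libs) {
  stopifnot(inherits(table, "ortholog_table"))
  if (is.null(names(libs)) || any(!nzchar(names(libs)))) {
    stop("'libs' must be a named list of tag libraries")
  }
  for (l in libs) stopifnot(inherits(l, "tag_library"))
  species <- names(libs)
  g <- table$genes
  counts <- matrix(0, nrow = nrow(g), ncol = length(species),
                   dimnames = list(g$gene_id, species))
  grp <- rep.int(seq_len(nrow(g)), g$n_tags)
  all_tags <- unlist(g$tags, use.names = FALSE)
  for (s in species) {
    cn <- libs[[s]]$counts[all_tags]
    if (anyNA(cn)) {
      stop("tag(s) missing from library '", s, "'")
    }
    counts[, s] <- as.numeric(rowsum(as.numeric(cn), grp,
                                     reorder = TRUE))
  }
  totals <- vapply(libs, `[[`, 0, "total")
  tpm_mat <- counts
  for (s in species) tpm_mat[, s] <- tpm(counts[, s], totals[[s]])
  table$counts <- counts
  table$tpm <- tpm_mat
  table$lib_totals <- totals
  table
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat("Ortholog table (database order: ",
      paste(x$db_order, collapse = " > "), ")\n", sep = "")
  cat("  genes: ", nrow(x$genes), "\n", sep = "")
  tab <- table(factor(x$genes$source_db, levels = x$db_order))
  for (db in x$db_order) {
    cat("    from ", db, ": ", tab[[db]], "\n", sep = "")
  }
  cat("  ambiguous tags: ", length(x$ambiguous_tags), "\n", sep = "")
  cat("  unmatched tags: ", length(x$unmatched_tags), "\n", sep = "")
  if (!is.null(x$counts)) {
    cat("  counts/TPM filled for: ",
        paste(colnames(x$counts), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write an ortholog table to TSV
#'
#' One row per gene: identifier, source database, member tags
#' (comma-separated) and, when filled, count and TPM per species. Ambiguous
#' and unmatched tags go to side files `<path>.ambiguous.txt` /
#' `<path>.unmatched.txt`.
#'
#' @param table An `ortholog_table`.
#' @param path Output TSV path.
#' @param header_comment Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(table, path, header_comment = NULL) {
  stopifnot(inherits(table, "ortholog_table"))
  df <- table$genes
  out <- data.frame(gene_id = df$gene_id, source_db = df$source_db,
                    n_tags = df$n_tags,
                    tags = vapply(df$tags, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  if (!is.null(table$counts)) {
    for (s in colnames(table$counts)) {
      out[[paste0("count.", s)]] <- table$counts[, s]
      out[[paste0("tpm.", s)]] <- table$tpm[, s]
    }
  }
  con <- file(path, "w")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  writeLines(table$ambiguous_tags, paste0(path, ".ambiguous.txt"))
  writeLines(table$unmatched_tags, paste0(path, ".unmatched.txt"))
  invisible(path)
}
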