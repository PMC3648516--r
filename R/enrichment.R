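#' Annotation map (term -> gene set)
#'
#' @param genes Named list: term identifier -> character vector of gene
#'   identifiers (each nonempty).
#' @param description Named character vector of term descriptions (optional,
#'   matched by term id).
#' @param category Named character vector of term categories (e.g. GO
#'   ontology or "KEGG"); terms without one get `"default"`. Enrichment is
#'   computed per category.
#' @param level Named integer vector of term levels (GO level metadata);
#'   carried through to output only.
#' @return Object of class `annotation_map`.
#' @export
annotation_map <- function(genes, description = NULL, category = NULL,
                           level = NULL) {
  if (!is.list(genes) || is.null(names(genes)) || any(!nzchar(names(genes)))) {
    stop("'genes' must be a named list of gene-id vectors")
  }
  if (any(lengths(genes) == 0L)) {
    stop("every term must annotate at least one gene")
  }
  genes <- lapply(genes, function(g) sort(unique(as.character(g))))
  ids <- names(genes)
  pick <- function(v, default) {
    out <- rep(default, length(ids)); names(out) <- ids
    if (!is.null(v)) out[intersect(names(v), ids)] <- v[intersect(names(v), ids)]
    out
  }
  structure(
    list(genes = genes,
         description = pick(description, NA_character_),
         category = pick(category, "default"),
         level = pick(level, NA_integer_)),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map: ", length(x$genes), " terms, ",
      length(unique(unlist(x$genes, use.names = FALSE))), " distinct genes\n",
      sep = "")
  print(table(x$category))
  invisible(x)
}

#' Read a GMT-like annotation file
#'
#' Standard GMT layout: one term per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. An optional metadata
#' TSV supplies `term_id`, `category` and/or `level` columns.
#'
#' @param path GMT file path.
#' @param meta_path Optional metadata TSV path.
#' @return An [annotation_map()].
#' @export
read_gmt <- function(path, meta_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(utils::head(which(short), 5L), collapse = ", "))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate term identifiers in GMT")
  desc <- vapply(parts, `[[`, "", 2L)
  genes <- lapply(parts, function(p) p[-(1:2)])
  names(genes) <- ids
  names(desc) <- ids
  category <- NULL; level <- NULL
  if (!is.null(meta_path)) {
    md <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    if (!"term_id" %in% names(md)) stop("metadata needs a 'term_id' column")
    if ("category" %in% names(md)) {
      category <- stats::setNames(md$category, md$term_id)
    }
    if ("level" %in% names(md)) {
      level <- stats::setNames(as.integer(md$level), md$term_id)
    }
  }
  annotation_map(genes, description = desc, category = category, level = level)
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `m` marked genes when drawing `n`
#' genes without replacement from a universe of `N` genes of which `M` are
#' marked:
#' \deqn{p = 1 - \sum_{i=0}^{m-1} \frac{\binom{M}{i}\binom{N-M}{n-i}}
#'   {\binom{N}{n}}.}
#' In enrichment use, `N`/`n` are the annotated universe and annotated DEG
#' counts and `M`/`m` the genes/DEGs annotated to one term.
#'
#' @param m,M,n,N Integers with `0 <= m <= min(n, M)`, `M <= N`, `n <= N`.
#' @return Upper-tail probability `P(X >= m)` in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(m, M, n, N) {
  k <- max(length(m), length(M), length(n), length(N))
  m <- rep_len(m, k); M <- rep_len(M, k)
  n <- rep_len(n, k); N <- rep_len(N, k)
  if (any(m < 0) || any(M > N) || any(n > N) || any(m > pmin(n, M))) {
    stop("require 0 <= m <= min(n, M), M <= N, n <= N")
  }
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Term enrichment of a DEG set by the hypergeometric test
#'
#' For each annotation category separately, restricts the universe and the
#' DEG set to genes carrying at least one annotation in that category
#' (giving `N` and `n`), drops terms annotating fewer than `min_term_size`
#' universe genes, and scores every surviving term with
#' [hypergeom_upper_tail()]. A term is enriched when `p <= alpha`.
#'
#' @param deg_genes Character vector of DEG identifiers (subset of
#'   `universe`).
#' @param annotation An [annotation_map()].
#' @param universe Character vector of all analysed gene identifiers (the
#'   ortholog table's genes).
#' @param min_term_size Terms with fewer universe genes are filtered out
#'   before testing (default 5).
#' @param alpha Inclusive significance level for the enriched flag
#'   (default 0.05). No multiple-testing correction is applied to the flag;
#'   a BH-adjusted column (`fdr`) is provided for reference.
#' @param warn_unknown Warn about annotated genes absent from the universe
#'   (default `TRUE`; such genes are always ignored).
#' @return data.frame of class `enrichment_table`, sorted by ascending
#'   p-value (ties broken by term id): `term_id`, `category`, `level`,
#'   `description`, `m`, `M`, `n`, `N`, `p_value`, `fdr`, `enriched`.
#' @export
enrich <- function(deg_genes, annotation, universe,
                   min_term_size = 5, alpha = 0.05, warn_unknown = TRUE) {
  stopifnot(inherits(annotation, "annotation_map"))
  universe <- unique(as.character(universe))
  deg_genes <- unique(as.character(deg_genes))
  if (!all(deg_genes %in% universe)) {
    stop("DEG set contains genes outside the universe: ",
         paste(utils::head(setdiff(deg_genes, universe), 5L), collapse = ", "))
  }
  unknown <- setdiff(unlist(annotation$genes, use.names = FALSE), universe)
  if (length(unknown) && warn_unknown) {
    warning(length(unknown),
            " annotated gene(s) not in the universe are ignored")
  }
  cats <- unique(annotation$category)
  res <- list()
  for (cc in cats) {
    term_ids <- names(annotation$genes)[annotation$category == cc]
    cat_genes <- unique(unlist(annotation$genes[term_ids], use.names = FALSE))
    n_univ <- intersect(cat_genes, universe)      # annotated universe
    if (!length(n_univ)) {
      stop("no universe gene carries an annotation in category '", cc, "'")
    }
    n_deg <- intersect(deg_genes, n_univ)
    N <- length(n_univ); n <- length(n_deg)
    for (tid in term_ids) {
      tg <- intersect(annotation$genes[[tid]], universe)
      M <- length(tg)
      if (M < min_term_size) next
      m <- length(intersect(tg, n_deg))
      res[[length(res) + 1L]] <- data.frame(
        term_id = tid, category = cc,
        level = annotation$level[[tid]],
        description = annotation$description[[tid]],
        m = m, M = M, n = n, N = N,
        p_value = hypergeom_upper_tail(m, M, n, N),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    out <- data.frame(term_id = character(0), category = character(0),
                      level = integer(0), description = character(0),
                      m = integer(0), M = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      fdr = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_value)
  out$enriched <- out$p_value <= alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table to TSV
#'
#' Columns mirror the usual published layout: term, level, description,
#' number of DEGs in the term, number of genes in the term, p-value.
#'
#' @param x An `enrichment_table`.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(x, path, header_comment = NULL) {
  con <- file(path, "w")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}
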