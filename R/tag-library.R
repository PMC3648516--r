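#' Construct a tag library from tags and counts
#'
#' @param tags Character vector of 21-mer tags.
#' @param counts Integer vector of copy numbers, same length as `tags`.
#' @param species_label Library label.
#' @param cleaned Whether the library has already passed [clean_tags()].
#' @return An object of class `tag_library`: list with `species_label`,
#'   `counts` (named integer vector, one entry per distinct tag),
#'   `total` (sum of counts), `distinct` (number of distinct tags) and
#'   `cleaned`.
#' @export
tag_library <- function(tags, counts, species_label, cleaned = FALSE) {
  if (length(tags) != length(counts)) stop("'tags' and 'counts' lengths differ")
  if (anyDuplicated(tags)) stop("duplicate tags in library input")
  counts <- as.integer(counts)
  if (length(counts) && (anyNA(counts) || any(counts < 1L))) {
    stop("counts must be positive integers")
  }
  cn <- counts
  names(cn) <- tags
  structure(
    list(species_label = species_label,
         counts = cn,
         total = sum(as.numeric(cn)),
         distinct = length(cn),
         cleaned = cleaned),
    class = "tag_library"
  )
}

#' @export
print.tag_library <- function(x, ...) {
  cat("Tag library (", x$species_label, ")",
      if (isTRUE(x$cleaned)) " [cleaned]", "\n", sep = "")
  cat("  total tags: ", format(x$total, big.mark = ","), "\n", sep = "")
  cat("  distinct tags: ", format(x$distinct, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Load a raw tag-count table
#'
#' Reads a two-column TSV (tag, count). A header line is detected
#' automatically (second field not an integer) and skipped. Rows with a
#' non-integer count, a tag that is not a 21-mer, a tag not starting with
#' `CATG`, or characters outside `ACGT` are malformed.
#'
#' @param path Path to the TSV file.
#' @param species_label Library label; defaults to the file name without
#'   extension.
#' @param on_malformed `"error"` (default) aborts listing the offending
#'   rows; `"skip"` drops them with a warning. The strict default keeps
#'   loading deterministic and loud.
#' @return A raw (uncleaned) `tag_library`.
#' @export
read_tag_counts <- function(path, species_label = NULL,
                            on_malformed = c("error", "skip")) {
  on_malformed <- match.arg(on_malformed)
  if (is.null(species_label)) {
    species_label <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tag_library(character(0), integer(0), species_label))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- parts[[1L]]
  has_header <- length(first) >= 2L && !grepl("^[0-9]+$", first[2L])
  if (has_header) {
    parts <- parts[-1L]
    if (!length(parts)) {
      return(tag_library(character(0), integer(0), species_label))
    }
  }
  tags <- vapply(parts, function(p) if (length(p) >= 1L) p[1L] else "", "")
  cnts <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", "")
  bad <- lengths(parts) != 2L |
    !grepl("^[0-9]+$", cnts) |
    !valid_tag(tags)
  if (any(bad)) {
    rows <- which(bad) + has_header
    msg <- paste0("malformed tag-count row(s) at line ",
                  paste(utils::head(rows, 10L), collapse = ", "),
                  if (sum(bad) > 10L) sprintf(" (and %d more)", sum(bad) - 10L))
    if (on_malformed == "error") stop(msg) else warning(msg, "; rows skipped")
    tags <- tags[!bad]
    cnts <- cnts[!bad]
  }
  tag_library(tags, as.integer(cnts), species_label)
}

# 21-mer, CATG prefix, ACGT alphabet
valid_tag <- function(tags) grepl("^CATG[ACGT]{17}$", tags)

#' Write a tag library as a two-column TSV
#'
#' @param lib A `tag_library`.
#' @param path Output path.
#' @param header_comment Optional character vector written as leading
#'   `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_tag_counts <- function(lib, path, header_comment = NULL) {
  stopifnot(inherits(lib, "tag_library"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  writeLines("tag\tcount", con)
  if (lib$distinct > 0L) {
    writeLines(paste(names(lib$counts), lib$counts, sep = "\t"), con)
  }
  invisible(path)
}

#' Remove singleton and malformed tags from a library
#'
#' Tags with a copy number of 1 are most plausibly sequencing errors in a
#' deeply sequenced DGE library and are discarded; so is any tag violating
#' the `CATG` + 17-nt format. Totals are recomputed. The operation is
#' idempotent.
#'
#' @param lib A `tag_library`.
#' @return A cleaned `tag_library` (every retained count is >= 2).
#' @export
clean_tags <- function(lib) {
  stopifnot(inherits(lib, "tag_library"))
  keep <- lib$counts >= 2L & valid_tag(names(lib$counts))
  out <- tag_library(names(lib$counts)[keep], lib$counts[keep],
                     lib$species_label, cleaned = TRUE)
  out
}

#' Distinct-tag counts per copy-number bin
#'
#' Summarises how many distinct tags fall into each half-open copy-number
#' interval `[e_i, e_{i+1})`, the last bin extending to infinity — the
#' tag-abundance distribution used to inspect library normality.
#'
#' @param lib A `tag_library`.
#' @param bin_edges Strictly ascending integer edges; bin `i` is
#'   `[edges[i], edges[i+1])`, the final bin `[edges[k], Inf)`. All copy
#'   numbers in the library must be `>= bin_edges[1]`.
#' @return Named integer vector of distinct-tag counts per bin; the names
#'   give the intervals. Sums to `lib$distinct`.
#' @export
tag_abundance_distribution <- function(lib, bin_edges) {
  stopifnot(inherits(lib, "tag_library"))
  if (length(bin_edges) < 1L) stop("at least one bin edge required")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin edges must be strictly ascending")
  }
  labs <- c(
    if (length(bin_edges) > 1L)
      sprintf("[%s,%s)", utils::head(bin_edges, -1L), bin_edges[-1L]),
    sprintf("[%s,Inf)", bin_edges[length(bin_edges)])
  )
  out <- integer(length(labs))
  names(out) <- labs
  if (lib$distinct == 0L) return(out)
  if (any(lib$counts < bin_edges[1L])) {
    stop("copy numbers below the first bin edge")
  }
  idx <- findInterval(lib$counts, bin_edges)
  tab <- tabulate(idx, nbins = length(labs))
  out[] <- tab
  out
}
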