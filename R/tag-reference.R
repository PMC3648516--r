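#' Build an in-silico tag reference index from a transcriptome
#'
#' Scans every transcript for occurrences of the NlaIII recognition site
#' (`CATG`) and records, for each occurrence followed by at least 17
#' nucleotides, the 21-mer tag beginning at that site (the MmeI cut yields
#' `CATG` + 17 nt). The result maps each possible tag to the set of
#' transcripts containing it, which is the reference database that observed
#' sequencing tags are matched against.
#'
#' @param transcripts A named character vector of nucleotide sequences, or a
#'   [Biostrings::DNAStringSet]. Names are transcript identifiers and must be
#'   unique.
#' @param species_label Label for the species/assembly the index represents.
#' @param antisense If `TRUE`, tags are additionally extracted from the
#'   reverse-complement strand. Defaults to `FALSE`: DGE tags derive from
#'   oriented cDNA, so only the sense strand is indexed.
#' @param site `"all"` indexes every CATG occurrence with 17 nt of
#'   downstream sequence (every tag the library could in principle contain);
#'   `"three_prime_most"` keeps only the 3'-most such site per transcript,
#'   emulating classic SAGE tag extraction.
#'
#' @details Candidate 21-mers containing any character outside `A`, `C`,
#' `G`, `T` (e.g. IUPAC ambiguity codes, `N`) are dropped; the rest of the
#' transcript still contributes tags. A tag occurring at several positions
#' of the same transcript is recorded once for that transcript.
#'
#' @return An object of class `tag_index`: a list with elements
#'   `species_label`, `index` (named list mapping each 21-mer tag to a
#'   character vector of transcript identifiers, keys sorted), and
#'   `n_transcripts`.
#' @seealso [read_transcriptome_fasta()], [assign_orthologs()]
#' @examples
#' tx <- c(t1 = paste0("GG", "CATG", strrep("A", 17), "CC"))
#' idx <- build_tag_index(tx, "demo")
#' names(idx$index)
#' @export
build_tag_index <- function(transcripts, species_label,
                            antisense = FALSE,
                            site = c("all", "three_prime_most")) {
  site <- match.arg(site)
  if (inherits(transcripts, "DNAStringSet")) {
    transcripts <- as.character(transcripts)
  }
  if (!is.character(transcripts)) {
    stop("'transcripts' must be a named character vector or DNAStringSet")
  }
  n_tx <- length(transcripts)
  if (n_tx > 0L && (is.null(names(transcripts)) || any(!nzchar(names(transcripts))))) {
    stop("all transcripts must be named")
  }
  dup <- names(transcripts)[duplicated(names(transcripts))]
  if (length(dup)) {
    stop("duplicate transcript identifier(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(transcripts)
  if (antisense) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
    names(rc) <- names(seqs)
  }

  tag_vec <- character(0)
  id_vec <- character(0)
  harvest <- function(seq_set) {
    out_tags <- vector("list", length(seq_set))
    for (i in seq_along(seq_set)) {
      out_tags[[i]] <- extract_tags(seq_set[[i]], site)
    }
    out_tags
  }
  if (n_tx > 0L) {
    sense <- harvest(seqs)
    if (antisense) {
      anti <- harvest(rc)
      sense <- mapply(function(a, b) unique(c(a, b)), sense, anti, SIMPLIFY = FALSE)
    } else {
      sense <- lapply(sense, unique)
    }
    lens <- lengths(sense)
    tag_vec <- unlist(sense, use.names = FALSE)
    id_vec <- rep.int(names(seqs), lens)
  }

  index <- if (length(tag_vec)) {
    m <- split(id_vec, tag_vec)        # split() sorts keys: deterministic
    lapply(m, function(v) sort(unique(v)))
  } else {
    structure(list(), names = character(0))
  }
  structure(
    list(species_label = species_label, index = index, n_transcripts = n_tx),
    class = "tag_index"
  )
}

# All valid CATG+17 tags of one sequence (character scalar, uppercase).
extract_tags <- function(seq, site = "all") {
  starts <- gregexpr("CATG", seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(character(0))
  starts <- starts[starts + 20L <= nchar(seq)]
  if (!length(starts)) return(character(0))
  if (site == "three_prime_most") starts <- max(starts)
  tags <- substring(seq, starts, starts + 20L)
  tags[grepl("^[ACGT]{21}$", tags)]
}

#' @export
print.tag_index <- function(x, ...) {
  cat("Tag reference index (", x$species_label, ")\n", sep = "")
  cat("  transcripts: ", x$n_transcripts, "\n", sep = "")
  cat("  distinct tags: ", length(x$index), "\n", sep = "")
  multi <- sum(lengths(x$index) > 1L)
  cat("  tags hitting >1 transcript: ", multi, "\n", sep = "")
  invisible(x)
}

#' Read a transcriptome assembly from FASTA
#'
#' @param path Path to a (possibly line-wrapped) multi-record FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_transcriptome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a transcriptome to FASTA
#'
#' @param transcripts Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcripts, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(transcripts), path)
  invisible(path)
}

#' Serialise a tag index to TSV
#'
#' Two columns: tag and a comma-separated list of transcript identifiers.
#'
#' @param index A `tag_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tag_index <- function(index, path) {
  stopifnot(inherits(index, "tag_index"))
  df <- data.frame(
    tag = names(index$index),
    transcripts = vapply(index$index, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
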