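#' Tags per million
#'
#' Scales a tag count by one million over the library's total clean-tag
#' count, the normalisation that makes expression levels comparable between
#' libraries of different depth.
#'
#' @param count Nonnegative count(s).
#' @param total_clean Positive library total (clean tags).
#' @return `count * 1e6 / total_clean`.
#' @export
tpm <- function(count, total_clean) {
  if (length(total_clean) != 1L || !is.finite(total_clean) || total_clean <= 0) {
    stop("'total_clean' must be a single positive number")
  }
  if (any(count < 0)) stop("counts must be nonnegative")
  count * 1e6 / total_clean
}

#' Expression-level category of a TPM value
#'
#' Default convention: low expression is TPM < 5, high expression is
#' TPM > 50, mid is the closed interval in between — i.e. bins
#' `[0, e1)`, `[e1, e2]`, `(e2, Inf)`.
#'
#' @param tpm_value Nonnegative TPM value(s).
#' @param edges Two ascending positive boundaries, default `c(5, 50)`.
#' @param labels Category labels, default `c("low", "mid", "high")`.
#' @return Factor of categories, levels in `labels` order.
#' @export
bin_expression <- function(tpm_value, edges = c(5, 50),
                           labels = c("low", "mid", "high")) {
  if (length(edges) != 2L || is.unsorted(edges, strictly = TRUE)) {
    stop("'edges' must be two strictly ascending values")
  }
  if (any(!is.finite(tpm_value)) || any(tpm_value < 0)) {
    stop("TPM values must be finite and nonnegative")
  }
  out <- ifelse(tpm_value < edges[1L], labels[1L],
                ifelse(tpm_value <= edges[2L], labels[2L], labels[3L]))
  factor(out, levels = labels)
}

#' A single qPCR measurement
#'
#' @param gene_id Gene identifier.
#' @param species Sample/species label.
#' @param ct_target Average threshold cycle of the target gene (over
#'   technical replicates).
#' @param ct_reference Threshold cycle of the endogenous reference gene
#'   (e.g. beta-actin) in the same sample.
#' @return An object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(gene_id, species, ct_target, ct_reference) {
  for (v in list(ct_target, ct_reference)) {
    if (!is.finite(v) || v <= 0) stop("CT values must be positive and finite")
  }
  structure(list(gene_id = gene_id, species = species,
                 ct_target = ct_target, ct_reference = ct_reference),
            class = "qpcr_measurement")
}

#' Read a qPCR CT table
#'
#' @param path TSV with columns `gene_id`, `species`, `ct_target`,
#'   `ct_reference`.
#' @return data.frame with those columns.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "ct_target", "ct_reference")
  if (!all(need %in% names(df))) {
    stop("qPCR table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' Relative expression by the comparative CT (2^-ddCT) method
#'
#' For one gene measured in two samples, computes
#' `2^-(dCT_a - dCT_b)` with `dCT = ct_target - ct_reference` per sample:
#' the expression of the gene in sample `a` relative to sample `b`, each
#' normalised to the reference gene.
#'
#' @param a,b [qpcr_measurement] objects for the same gene in two samples.
#' @return The relative expression ratio (sample `a` over sample `b`).
#' @export
relative_expression_ddct <- function(a, b) {
  stopifnot(inherits(a, "qpcr_measurement"), inherits(b, "qpcr_measurement"))
  if (!identical(a$gene_id, b$gene_id)) {
    stop("measurements are for different genes: ",
         a$gene_id, " vs ", b$gene_id)
  }
  dct_a <- a$ct_target - a$ct_reference
  dct_b <- b$ct_target - b$ct_reference
  2^-(dct_a - dct_b)
}

#' Direction concordance between DGE and qPCR fold changes
#'
#' A gene is concordant when its DGE and qPCR log2 fold changes are both
#' nonzero and share the same sign; a zero on either side counts as
#' discordant.
#'
#' @param log2_dge,log2_qpcr Numeric vectors of equal length.
#' @return List with `n_concordant` and `n_total`.
#' @export
direction_concordance <- function(log2_dge, log2_qpcr) {
  if (length(log2_dge) != length(log2_qpcr)) {
    stop("fold-change vectors must have equal length")
  }
  if (any(!is.finite(c(log2_dge, log2_qpcr)))) {
    stop("fold changes must be finite")
  }
  conc <- sign(log2_dge) != 0 & sign(log2_dge) == sign(log2_qpcr)
  list(n_concordant = sum(conc), n_total = length(log2_dge))
}
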