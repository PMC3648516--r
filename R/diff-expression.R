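#' Exact two-library tag-count test (Audic-Claverie)
#'
#' Tests whether a tag (gene) count differs between two libraries of known
#' size beyond sampling noise. Conditional on observing `x` copies in a
#' library of `n1` tags, the count `y` in an independent library of `n2`
#' tags follows
#' \deqn{P(y \mid x) = \left(\frac{n_2}{n_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + n_2/n_1)^{x+y+1}},}
#' the posterior-predictive distribution of the second count under a flat
#' prior on the common per-tag rate. The two-sided p-value doubles the
#' smaller tail, capped at 1:
#' `p = min(1, 2 min(P(Y <= y), P(Y >= y)))`.
#'
#' @param x,y Observed nonnegative integer counts in the two libraries
#'   (vectors are recycled against each other).
#' @param n1,n2 Positive library totals (clean tags) for the libraries of
#'   `x` and `y` respectively.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @details Probabilities are accumulated in log space (log-gamma terms and
#' a shifted exponential sum), so counts of order 10^4-10^5 in libraries of
#' millions of tags are handled without overflow. The test is symmetric
#' under the simultaneous swap `(x, n1) <-> (y, n2)`.
#' @references Audic S, Claverie JM (1997) The significance of digital
#' gene expression profiles. Genome Research 7:986-995.
#' @export
exact_tag_test <- function(x, y, n1, n2) {
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    stop("counts must be nonnegative integers")
  }
  vapply(seq_len(k), function(i) ac_two_sided(x[i], y[i], n1[i], n2[i]), 0)
}

# log P(y'|x) for y' = 0..ymax, by the log-space recurrence
# lp(0) = (x+1) log(n1/(n1+n2));
# lp(y'+1) - lp(y') = log(n2/(n1+n2)) + log((x+y'+1)/(y'+1))
ac_log_pmf <- function(x, ymax, n1, n2) {
  lr <- log(n2) - log(n1 + n2)
  lp0 <- (x + 1) * (log(n1) - log(n1 + n2))
  if (ymax == 0) return(lp0)
  yy <- seq_len(ymax)
  inc <- lr + log(x + yy) - log(yy)
  c(lp0, lp0 + cumsum(inc))
}

ac_two_sided <- function(x, y, n1, n2) {
  lp <- ac_log_pmf(x, y, n1, n2)
  m <- max(lp)
  lower <- exp(m) * sum(exp(lp - m))          # P(Y <= y)
  pmf_y <- exp(lp[y + 1L])
  upper <- 1 - lower + pmf_y                  # P(Y >= y)
  upper <- min(max(upper, 0), 1)
  lower <- min(lower, 1)
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values): with ordered p-values `p_(1) <=
#' ... <= p_(m)`, `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1, returned
#' in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input; elementwise `>=`
#'   the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Log2 ratio of normalised counts
#'
#' `log2(((y + pseudocount)/n2) / ((x + pseudocount)/n1))`: the fold change
#' of the second library over the first on the normalised (per-library-
#' total) scale. A positive pseudocount is required when either count is
#' zero, where the raw ratio is undefined.
#'
#' @param x,y Counts in the first and second library.
#' @param n1,n2 Library totals.
#' @param pseudocount Nonnegative value added to both counts before
#'   normalisation; default 1 tag.
#' @return log2 fold change(s), second library over first.
#' @export
log2_ratio <- function(x, y, n1, n2, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  if (pseudocount == 0 && any(x == 0 | y == 0)) {
    stop("zero count with zero pseudocount: ratio undefined")
  }
  log2(((y + pseudocount) / n2) / ((x + pseudocount) / n1))
}

#' Classify a gene's differential-expression status
#'
#' A gene is called `up` when `fdr < fdr_threshold` and
#' `log2_ratio >= lfc_threshold`, `down` when `fdr < fdr_threshold` and
#' `log2_ratio <= -lfc_threshold`, otherwise `ns`. The FDR cut is strict
#' and the fold-change cut inclusive.
#'
#' @param fdr,log2_ratio Numeric vectors.
#' @param fdr_threshold Strict FDR cutoff, default 0.001.
#' @param lfc_threshold Inclusive |log2 ratio| cutoff, default 1.
#' @return Factor with levels `up`, `down`, `ns`.
#' @export
deg_status <- function(fdr, log2_ratio, fdr_threshold = 0.001,
                       lfc_threshold = 1) {
  sig <- fdr < fdr_threshold
  out <- ifelse(sig & log2_ratio >= lfc_threshold, "up",
                ifelse(sig & log2_ratio <= -lfc_threshold, "down", "ns"))
  factor(out, levels = c("up", "down", "ns"))
}

#' Call differentially expressed genes between two species
#'
#' Runs the exact tag test on every ortholog gene for one species pair,
#' adjusts p-values by Benjamini-Hochberg across all genes of the
#' comparison, computes normalised log2 fold changes, and classifies each
#' gene.
#'
#' @param table An `ortholog_table` with counts filled by [gene_counts()].
#' @param species_a,species_b Column names of the comparison; the reported
#'   ratio is `species_b` over `species_a` (genes `up` are higher in
#'   `species_b`).
#' @param fdr_threshold,lfc_threshold See [deg_status()].
#' @param pseudocount See [log2_ratio()].
#' @return data.frame of class `deg_table` with one row per gene:
#'   `gene_id`, `x`, `y` (counts in a and b), `n1`, `n2`, `tpm_a`, `tpm_b`,
#'   `log2_ratio`, `p_value`, `fdr`, `status`. Attributes `species_a`,
#'   `species_b` record the comparison.
#' @export
call_degs <- function(table, species_a, species_b,
                      fdr_threshold = 0.001, lfc_threshold = 1,
                      pseudocount = 1) {
  stopifnot(inherits(table, "ortholog_table"))
  if (is.null(table$counts)) stop("run gene_counts() before call_degs()")
  for (s in c(species_a, species_b)) {
    if (!s %in% colnames(table$counts)) {
      stop("species '", s, "' not present in the ortholog table counts")
    }
  }
  x <- table$counts[, species_a]
  y <- table$counts[, species_b]
  n1 <- table$lib_totals[[species_a]]
  n2 <- table$lib_totals[[species_b]]
  p <- exact_tag_test(x, y, n1, n2)
  q <- bh_fdr(p)
  lfc <- log2_ratio(x, y, n1, n2, pseudocount)
  out <- data.frame(
    gene_id = table$genes$gene_id,
    x = as.integer(x), y = as.integer(y),
    n1 = n1, n2 = n2,
    tpm_a = table$tpm[, species_a], tpm_b = table$tpm[, species_b],
    log2_ratio = lfc, p_value = p, fdr = q,
    status = deg_status(q, lfc, fdr_threshold, lfc_threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "species_a") <- species_a
  attr(out, "species_b") <- species_b
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Write a DEG table to TSV
#'
#' @param degs A `deg_table` from [call_degs()].
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(degs, path, header_comment = NULL) {
  con <- file(path, "w")
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(as.data.frame(degs), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}
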