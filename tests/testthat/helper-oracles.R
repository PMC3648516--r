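# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's code paths (no recurrences, no shared helpers).

# every CATG-anchored 21-mer of a sequence, by a plain position scan
oracle_scan_tags <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- character(0)
  if (n < 21) return(out)
  for (i in seq_len(n - 20)) {
    w <- substr(seq, i, i + 20)
    if (substr(w, 1, 4) == "CATG" && !grepl("[^ACGT]", w)) {
      out <- c(out, w)
    }
  }
  unique(out)
}

# Audic-Claverie conditional pmf term, straight from the closed form
oracle_ac_pmf <- function(yp, x, n1, n2) {
  exp(yp * (log(n2) - log(n1)) +
        lgamma(x + yp + 1) - lgamma(x + 1) - lgamma(yp + 1) -
        (x + yp + 1) * log1p(n2 / n1))
}

# two-sided p by direct summation of the pmf over the tails
oracle_ac_p <- function(x, y, n1, n2, ymax = NULL) {
  if (is.null(ymax)) ymax <- 10 * (x + y) + 200
  yy <- 0:ymax
  terms <- oracle_ac_pmf(yy, x, n1, n2)
  lower <- sum(terms[yy <= y])
  upper <- sum(terms[yy >= y])
  min(1, 2 * min(lower, upper))
}

# naive O(m^2) Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(m, M, n, N) {
  draws <- utils::combn(N, n)                 # marked genes are 1..M
  hits <- colSums(draws <= M)
  mean(hits >= m)
}

# hypergeometric upper tail by direct binomial-coefficient summation
oracle_hyper_sum <- function(m, M, n, N) {
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# a random tag-library fixture
random_library <- function(n_tags, species = "X", max_count = 50,
                           singleton_fraction = 0) {
  tags <- unique(replicate(n_tags, paste0(
    "CATG", paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE),
                  collapse = ""))))
  counts <- sample(2:max_count, length(tags), replace = TRUE)
  if (singleton_fraction > 0) {
    ones <- seq_len(round(singleton_fraction * length(tags)))
    counts[ones] <- 1L
  }
  tag_library(tags, counts, species)
}
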