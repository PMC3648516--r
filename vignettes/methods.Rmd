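---
title: "Methods: cross-species DGE tag analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species DGE tag analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

# The model

`tagdge` analyses SAGE-like digital gene expression (DGE) libraries: a
transcript is represented by the 21-bp tags starting at each of its NlaIII
recognition sites (`CATG`) and running 17 nt downstream (the MmeI cut
distance), and its expression level by how often those tags were
sequenced. Because exact 21-mers are conserved between closely related
species, a tag observed in *every* species' library ties the same gene
across species, which is what makes between-species expression comparison
possible from independent single-species assemblies.

The pipeline has five statistical components, each exposed as a
standalone function and orchestrated by `run_pipeline()`.

## Tag references and cleaning

`build_tag_index()` enumerates *every* `CATG` occurrence followed by at
least 17 nt, on the sense strand only: DGE tags derive from oriented
cDNA, so antisense tags are off by default (an `antisense` flag exists,
and a `site = "three_prime_most"` mode emulates classic SAGE, which keeps
only the 3'-most site). Candidate windows containing non-`ACGT`
characters (IUPAC ambiguity codes) are dropped individually without
discarding the transcript. A tag repeated within one transcript maps to
it once — the index stores sets, not multisets.

`clean_tags()` removes tags with copy number 1. In a library of millions
of tags, a 21-mer seen exactly once is far more plausibly a sequencing
error than a real transcript, and the error model of the synthetic
generator (below) makes the same assumption. Cleaning is idempotent and
can only shrink a library.

## Ortholog assignment

`assign_orthologs()` resolves each common tag against the species
reference indexes in a fixed priority order (here: the best-annotated
assembly first). The tag is judged in the *first* database that contains
it: a unique hit assigns the gene, a multi-transcript hit discards the
tag as ambiguous, and a tag absent everywhere is unmatched. Two open
design points are worth stating:

* **Ambiguity scope.** An ambiguous tag is discarded outright rather than
  being given a second chance in later databases — a tag that cannot
  identify a unique gene in its best reference is unreliable evidence.
  The alternative reading (discard tags that are multi-hit in *any*
  database, before mapping) is available as `ambiguity = "joint"`.
* **Gene identity.** Genes are identified by the transcript they map to
  in their source database only; no cross-database sequence joining is
  attempted. The same underlying gene recovered once from database A and
  once (via different tags) from database B therefore appears as two
  records, which mirrors what exact-tag mapping can actually support.

The member tags of the assigned genes, the ambiguous tags and the
unmatched tags always partition the common-tag set — this conservation
property is asserted in the test suite and the acceptance run.

## Normalisation and expression categories

Counts are normalised to tags per million, TPM = count × 10⁶ /
*library total*. The denominator is the library's total **clean** tags,
not its mapped tags: "per million tags" refers to sequencing depth, and
using the mapped total would make a gene's TPM depend on how many *other*
tags happened to map. Summed over all tags of a library, TPM is exactly
10⁶; summed over assigned ortholog genes it is necessarily less. (The
mapped-total convention can be had by passing a different total to
`tpm()`.)

Expression categories use `[0, 5)` = low, `[5, 50]` = mid, `(50, ∞)` =
high; the boundary conventions honour the usual "low means TPM < 5" and
"high means TPM > 50" phrasing, which leaves both boundary values in the
mid class.

## The exact test

`exact_tag_test()` implements the Audic–Claverie statistic. Conditional
on count $x$ in a library of $n_1$ tags, the count $y$ of the same gene
in an independent library of $n_2$ tags follows

$$P(y \mid x) = \left(\frac{n_2}{n_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,\left(1 + n_2/n_1\right)^{x+y+1}},$$

the posterior predictive of a Poisson rate under a flat prior — which is
a negative binomial with size $x+1$ and success probability
$n_1/(n_1+n_2)$ (the suite uses `pnbinom` as an independent cross-check
of the summation). The two-sided p-value doubles the smaller of the
inclusive tails and caps at 1:

$$p = \min\bigl(1,\; 2\min(P(Y \le y),\, P(Y \ge y))\bigr).$$

Numerical choices: the log-pmf is accumulated by a log-space recurrence
(one `log` per step rather than three `lgamma`s), the lower tail is
summed after shifting by the maximum log term so that far-tail p-values
do not underflow termwise, and the upper tail is obtained as
$1 - P(Y \le y-1)$, whose absolute error is at the summation's
floating-point level. The suite verifies agreement with a direct
summation oracle to $10^{-10}$ over the full $x, y \le 200$ grid in
three library-size regimes, and that the pmf sums to one.

One property deserves a caveat: the doubled-tail p is *not* exactly
invariant under swapping the two libraries, because the inclusive lower
tail at $y$ given $x$ equals the *strict* upper tail at $x$ given $y$
(the tails trade a pmf term). The discrepancy vanishes as counts grow;
the tests assert the exact tail-swap identity rather than p-level
symmetry.

**Multiplicity and thresholds.** p-values are adjusted per comparison by
Benjamini–Hochberg step-up (`bh_fdr()`, delegating to `p.adjust`); a gene
is a DEG when FDR < 0.001 (strict) *and* |log₂ ratio| ≥ 1 (inclusive).
The log₂ ratio is computed on normalised counts with a default
pseudocount of 1 tag added to both counts — without it the ratio is
undefined whenever a gene is undetected in one species, and such
presence/absence genes are exactly the strongest candidates. The
pseudocount bounds reported fold changes at roughly
$\pm\log_2(\text{depth})$ and is configurable.

## Enrichment

`enrich()` scores each annotation term by the hypergeometric upper tail

$$p = 1 - \sum_{i=0}^{m-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

i.e. $P(X \ge m)$ — the sum runs to $m-1$, so the observed count itself
belongs to the tail. $N$ and $n$ are the universe genes and DEGs carrying
at least one annotation *in the term's category* (GO ontology or KEGG),
computed per category rather than globally: a gene with only molecular-
function annotations is not part of the biological-process universe, and
mixing categories would deflate every p-value. Terms annotating fewer
than 5 universe genes are removed before testing; the enriched flag is
the raw p ≤ 0.05 (inclusive), with a BH-adjusted column provided for
users who want it — the flag itself is deliberately uncorrected, matching
the common practice for these screens. Output is sorted by p with term-id
tie-breaks for determinism.

## qPCR concordance

`relative_expression_ddct()` implements $2^{-\Delta\Delta C_T}$ with
$\Delta C_T = C_T(\text{target}) - C_T(\text{reference})$ per sample;
`direction_concordance()` counts genes whose DGE and qPCR log₂ fold
changes are both nonzero with the same sign (zeros count as discordant —
a platform that calls "no change" has not confirmed a direction).

# The synthetic generator

`simulate_study()` produces data with the statistical structure the
analysis assumes, plus ground truth:

* **Transcriptomes.** One ancestral transcript per gene (uniform random
  sequence, 400–1200 nt by default, with one guaranteed internal `CATG`
  site so every gene is taggable); each species' copy is derived by
  independent per-site substitution at the configured `divergence`. A tag
  window therefore survives intact in one species with probability
  $(1-d)^{21}$ and in all three with $(1-d)^{63}$ — substitutions inside
  windows destroy common tags naturally, exercising the fallback mapping.
  The default $d = 0.01$ reflects the high coding-sequence conservation
  of cryptic-species complexes; values much above 0.05 leave few common
  tags (the generator warns, with statistics, rather than failing).
* **Expression.** Baseline expression is lognormal (sdlog 1.5, an
  RNA-seq-like spread over roughly four orders of magnitude), shared by
  all species, renormalised to 10⁶ TPM per species. Each planted DE gene
  (default 15% of genes, matching the DEG rates such comparisons report)
  has one randomly chosen species scaled by $2^{\pm 2}$.
* **Libraries.** Tags are drawn multinomially — gene proportional to true
  TPM, tag uniform within the gene — at a default depth of 10⁶ tags, with
  3% of raw mass injected as unique copy-number-1 error tags (the
  raw-vs-clean distinct-tag gap typical of deeply sequenced DGE
  libraries). Error tags are *only* singletons: no quality-score or
  read-level model is attempted, so cleaning removes exactly the noise
  class the generator emits plus genuinely rare true tags.
* **Annotations.** Random terms of 3–80 genes (some below the size-5
  filter by design) over species-qualified transcript ids, plus planted
  terms packed 90% with DE genes.

Everything is driven by one integer seed; identical configurations give
byte-identical outputs.

**What passing tests do and do not show.** The generator emulates the
sampling structure of tag libraries (multinomial counting noise,
singleton errors, sequence divergence), not their biological texture: no
paralog families, no indels, no 3'-bias, no replicate-level biological
variability (the test compares single libraries, as single-replicate DGE
designs do). Operating characteristics measured on synthetic data —
e.g. sensitivity for 4-fold effects at 10⁶ depth — therefore describe the
*statistical* pipeline under its own assumptions, not performance on any
real dataset.

# Validation scale and acceptance runs

The end-to-end acceptance runs use 2,000 genes at 10⁶ tags per library —
large enough that per-gene counts sit in the range where the exact test
operates (median a few hundred), small enough that the whole suite runs
in well under a minute. They are performed at zero sequence divergence
with singleton noise on: a diverged gene that loses all its common tags
never enters the ortholog table at all, so running the DE
characterisation at zero divergence isolates the test's sensitivity and
FDR from mapping attrition, which is exercised separately (the
survival-rate and fallback-mapping tests run at $d = 0.01$–$0.05$). With
planted $|\log_2| = 2$ effects on 15% of genes the pipeline recovers
85–90% of planted pair effects with zero false calls among them at
FDR < 0.001, and the no-effect run produces no spurious DEGs; both
numbers are recomputed from scratch by `scripts/acceptance.R`.

# Known limitations

* Exact matching only: no mismatch tolerance, no reverse-complement
  mapping, no reciprocal-best-hit orthology. Genes whose tags all diverge
  between species are invisible to the method.
* Single-replicate: the exact test models sampling noise only; biological
  dispersion between replicates is out of scope (a replicate-aware
  negative-binomial framework would be the tool of choice there).
* Annotation maps are inputs; the package does not build them from
  sequence homology.
* The per-database ambiguity rule and the pseudocount convention are
  defensible defaults, not claims about any particular published
  pipeline; both are configurable.
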