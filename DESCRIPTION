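Package: tagdge
Title: Cross-Species Digital Gene Expression Tag Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SAGE-like digital gene expression (DGE) tag profiling
    across related species. Builds in-silico reference databases of all
    CATG-anchored 21-bp tags from transcriptome assemblies, cleans and
    summarises tag-count libraries, identifies orthologous genes by exact
    sequential mapping of tags shared across libraries, normalises counts to
    tags per million (TPM), tests two-library count differences with the
    Audic-Claverie exact statistic under Benjamini-Hochberg false discovery
    rate control, and scores GO/KEGG term over-representation among
    differentially expressed genes with the hypergeometric upper tail.
    Includes a synthetic-data generator (divergent transcriptomes with known
    orthology, multinomially sampled tag libraries with planted fold changes
    and singleton sequencing-error tags) so the whole pipeline is testable
    end to end, and qPCR 2^-ddCt concordance utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
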