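small_cfg <- function(seed = 7, ...) {
  synthetic_config(n_genes = 150, gene_length = c(300, 600),
                   library_depth = 1e5, seed = seed, ...)
}

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$transcriptomes, b$transcriptomes)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$libraries, `[[`, "counts"),
                   lapply(b$libraries, `[[`, "counts"))
  expect_identical(names(a$annotation$genes), names(b$annotation$genes))
  # a different seed changes the data
  c2 <- simulate_study(small_cfg(seed = 8))
  expect_false(identical(a$transcriptomes, c2$transcriptomes))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synthetic_config(divergence = 0.5))
  expect_error(synthetic_config(singleton_noise_rate = 1))
  expect_error(synthetic_config(n_genes = 0))
  expect_error(synthetic_config(gene_length = c(10, 5)))
})

test_that("zero divergence makes all species' tag sets identical", {
  cfg <- small_cfg(divergence = 0)
  sim <- simulate_transcriptomes(cfg)
  tag_sets <- lapply(cfg$species, function(sp) {
    sort(unique(unlist(lapply(sim$transcriptomes[[sp]], oracle_scan_tags))))
  })
  expect_identical(tag_sets[[1]], tag_sets[[2]])
  expect_identical(tag_sets[[1]], tag_sets[[3]])
  # every gene carries at least one tag site by construction
  idx <- build_tag_index(sim$transcriptomes[[cfg$species[1]]], "s")
  expect_identical(length(unique(unlist(idx$index))), cfg$n_genes)
})

test_that("ancestral tag windows survive in all species at the per-site rate", {
  cfg <- synthetic_config(n_genes = 400, gene_length = c(300, 600),
                          divergence = 0.02, library_depth = 1e4, seed = 31)
  sim <- simulate_transcriptomes(cfg)
  surv <- 0L; tot <- 0L
  for (g in names(sim$ancestors)) {
    for (w in oracle_scan_tags(sim$ancestors[[g]])) {
      tot <- tot + 1L
      ok <- all(vapply(cfg$species, function(sp) {
        grepl(w, sim$transcriptomes[[sp]][[paste(sp, g, sep = "|")]],
              fixed = TRUE)
      }, TRUE))
      if (ok) surv <- surv + 1L
    }
  }
  # each of the 21 window sites must stay unmutated in all 3 species
  expected <- (1 - cfg$divergence)^(21 * length(cfg$species))
  tol <- 4 * sqrt(expected * (1 - expected) / tot) + 0.02  # overlap slack
  expect_lt(abs(surv / tot - expected), tol)

  # per-gene retention matches the window-survival oracle
  n_windows <- vapply(sim$ancestors,
                      function(s) length(oracle_scan_tags(s)), 0L)
  p_gene <- 1 - (1 - expected)^n_windows
  exp_frac <- mean(p_gene)
  sd_frac <- sqrt(sum(p_gene * (1 - p_gene))) / length(p_gene)
  expect_lt(abs(sim$common_tag_gene_fraction - exp_frac),
            4 * sd_frac + 0.03)
})

test_that("library gene counts track true TPM within multinomial error", {
  cfg <- small_cfg(singleton_noise_rate = 0, de_fraction = 0)
  study <- simulate_study(cfg, annotation = FALSE)
  sp <- cfg$species[1]
  idx <- build_tag_index(study$transcriptomes[[sp]], sp)
  lib <- study$libraries[[sp]]
  # recover per-gene totals by summing each gene's tag counts
  tag2gene <- unlist(lapply(names(idx$index), function(t) {
    stats::setNames(rep(idx$index[[t]][1], 1), t)
  }))
  obs <- tapply(as.numeric(lib$counts),
                sub(".*\\|", "", tag2gene[names(lib$counts)]), sum)
  truth <- study$truth
  exp_counts <- truth[[paste0("tpm.", sp)]] * cfg$library_depth / 1e6
  names(exp_counts) <- truth$gene_id
  keep <- names(obs)[exp_counts[names(obs)] >= 50]
  z <- (obs[keep] - exp_counts[keep]) / sqrt(exp_counts[keep])
  expect_lt(max(abs(z)), 6)
  expect_lt(abs(mean(z)), 1)
  # totals approximately at the configured depth
  expect_lt(abs(lib$total - cfg$library_depth) / cfg$library_depth, 0.02)
})

test_that("singleton noise adds the configured removable mass", {
  cfg <- small_cfg(singleton_noise_rate = 0.1)
  study <- simulate_study(cfg, annotation = FALSE)
  for (sp in cfg$species) {
    raw <- study$libraries[[sp]]
    cl <- clean_tags(raw)
    removed <- (raw$total - cl$total) / raw$total
    # noise singletons plus the occasional true singleton tag
    expect_gt(removed, 0.08)
    expect_lt(removed, 0.14)
    expect_true(all(cl$counts >= 2))
  }
})

test_that("planted fold changes are recovered by the normalised estimator", {
  cfg <- synthetic_config(n_genes = 500, library_depth = 1e6,
                          divergence = 0, de_fraction = 0.2,
                          effect_log2 = 2, singleton_noise_rate = 0,
                          seed = 41)
  study <- simulate_study(cfg, annotation = FALSE)
  a <- cfg$species[1]; b <- cfg$species[2]
  eff <- truth_effects(study$truth, a, b)
  la <- study$libraries[[a]]; lb <- study$libraries[[b]]
  idx <- build_tag_index(study$transcriptomes[[a]], a)
  # per-gene counts via the gene's own tags (zero divergence: shared tags)
  gene_tags <- lapply(study$orthology[[a]], function(tid) {
    oracle_scan_tags(study$transcriptomes[[a]][[tid]])
  })
  names(gene_tags) <- study$truth$gene_id
  count_of <- function(lib, tags) sum(lib$counts[tags], na.rm = TRUE)
  ta <- study$truth[[paste0("tpm.", a)]]
  tb <- study$truth[[paste0("tpm.", b)]]
  sel <- which(eff$is_de_pair & pmin(ta, tb) >= 300)
  expect_gt(length(sel), 5)
  for (i in sel) {
    x <- count_of(la, gene_tags[[i]])
    y <- count_of(lb, gene_tags[[i]])
    est <- log2_ratio(x, y, la$total, lb$total)
    expect_lt(abs(est - eff$true_log2[i]), 0.3)
  }
})

test_that("synthetic annotations group genes with planted enriched terms", {
  cfg <- small_cfg(de_fraction = 0.3)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(truth, cfg, n_terms = 30, n_enriched_terms = 2)
  expect_s3_class(ann, "annotation_map")
  # terms list species-qualified transcript ids for each member gene
  base <- lapply(ann$genes, function(g) unique(sub("^[^|]+\\|", "", g)))
  expect_true(all(lengths(ann$genes) == 3 * lengths(base)))
  expect_true(all(lengths(base) >= 3 & lengths(base) <= 80))
  det <- grep("^DETERM", names(base), value = TRUE)
  expect_length(det, 2)
  de <- truth$gene_id[truth$is_de]
  for (t in det) {
    expect_gt(mean(base[[t]] %in% de), 0.7)
  }
})
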