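# compact helpers for building tiny libraries/indexes from plain letters
mktag <- function(ch) paste0("CATG", strrep(ch, 17))
mklib <- function(tags, counts, sp) tag_library(tags, counts, sp, cleaned = TRUE)
mkindex <- function(species, mapping) {
  # mapping: named list tag -> transcript ids
  idx <- lapply(mapping, function(v) sort(unique(v)))
  idx <- idx[order(names(idx))]
  structure(list(species_label = species, index = idx,
                 n_transcripts = length(unique(unlist(mapping)))),
            class = "tag_index")
}

test_that("common tags are the exact multi-way intersection", {
  a <- mktag("A"); b <- mktag("C"); c3 <- mktag("G")
  l1 <- mklib(c(a, b), c(2, 3), "s1")
  l2 <- mklib(c(b, c3), c(4, 5), "s2")
  l3 <- mklib(b, 6, "s3")
  expect_identical(common_tags(list(l1, l2, l3)), b)
  expect_length(common_tags(list(mklib(a, 2, "s1"), mklib(b, 2, "s2"))), 0)
  expect_error(common_tags(list(l1)), "two")
})

test_that("random intersections equal a pairwise set-algebra fold", {
  set.seed(21)
  pool <- unique(replicate(300, paste0(
    "CATG", paste(sample(c("A", "C", "G", "T"), 17, TRUE), collapse = ""))))
  sets <- lapply(1:3, function(i) sample(pool, 150))
  libs <- lapply(1:3, function(i)
    mklib(sets[[i]], rep(2, length(sets[[i]])), paste0("s", i)))
  want <- intersect(intersect(sets[[1]], sets[[2]]), sets[[3]])
  expect_setequal(common_tags(libs), want)
})

test_that("sequential mapping honours priority, fallback and ambiguity", {
  tA <- mktag("A"); tC <- mktag("C"); tG <- mktag("G"); tT <- mktag("T")
  db1 <- mkindex("MED", setNames(list("m1", c("m2", "m3")), c(tA, tG)))
  db2 <- mkindex("MEAM1", setNames(list("b1", "b2", "b3"), c(tA, tC, tG)))
  tab <- assign_orthologs(c(tA, tC, tG, tT), list(db1, db2))

  # tA unique in db1 regardless of db2; tC absent from db1, falls to db2;
  # tG multi-hit in its first containing database -> discarded outright
  expect_identical(tab$genes$gene_id[tab$genes$tags %in% list(tA)][1], "m1")
  g <- tab$genes
  expect_identical(g$source_db[g$gene_id == "m1"], "MED")
  expect_identical(g$source_db[g$gene_id == "b2"], "MEAM1")
  expect_false("b3" %in% g$gene_id)
  expect_identical(tab$ambiguous_tags, tG)
  expect_identical(tab$unmatched_tags, tT)
  expect_error(assign_orthologs(tA, list()), "index")
})

test_that("joint ambiguity mode discards multi-hit tags before mapping", {
  tA <- mktag("A")
  db1 <- mkindex("d1", setNames(list("x1"), tA))
  db2 <- mkindex("d2", setNames(list(c("y1", "y2")), tA))
  per_db <- assign_orthologs(tA, list(db1, db2))
  joint <- assign_orthologs(tA, list(db1, db2), ambiguity = "joint")
  expect_identical(per_db$genes$gene_id, "x1")
  expect_identical(nrow(joint$genes), 0L)
  expect_identical(joint$ambiguous_tags, tA)
})

test_that("random 3-database partition matches a per-tag walk oracle", {
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  tags <- unique(replicate(200, paste0(
    "CATG", paste(sample(bases, 17, TRUE), collapse = ""))))
  dbs <- lapply(1:3, function(k) {
    hit <- tags[runif(length(tags)) < 0.5]
    mapping <- lapply(hit, function(t) {
      n_tx <- sample(1:2, 1, prob = c(.85, .15))
      paste0("db", k, "_tx", sample(500, n_tx))
    })
    names(mapping) <- hit
    mkindex(paste0("db", k), mapping)
  })
  tab <- assign_orthologs(tags, dbs)

  assigned <- unlist(tab$genes$tags, use.names = FALSE)
  # partition property
  expect_identical(sort(c(assigned, tab$ambiguous_tags, tab$unmatched_tags)),
                   sort(tags))
  expect_identical(anyDuplicated(assigned), 0L)
  expect_identical(anyDuplicated(tab$genes$gene_id), 0L)

  # per-tag priority walk
  for (t in tags) {
    res <- NULL
    for (k in 1:3) {
      hits <- dbs[[k]]$index[[t]]
      if (!is.null(hits)) {
        res <- if (length(hits) == 1) c("gene", hits) else "ambiguous"
        break
      }
    }
    if (is.null(res)) {
      expect_true(t %in% tab$unmatched_tags)
    } else if (identical(res, "ambiguous")) {
      expect_true(t %in% tab$ambiguous_tags)
    } else {
      gid <- tab$genes$gene_id[vapply(tab$genes$tags, function(v) t %in% v, TRUE)]
      expect_identical(gid, res[2])
    }
  }
})

test_that("reordering databases never creates overlapping member tags", {
  set.seed(34)
  tA <- mktag("A"); tC <- mktag("C"); tG <- mktag("G")
  db1 <- mkindex("d1", setNames(list("x1", "x2"), c(tA, tC)))
  db2 <- mkindex("d2", setNames(list("y1", "y2"), c(tC, tG)))
  for (ord in list(list(db1, db2), list(db2, db1))) {
    tab <- assign_orthologs(c(tA, tC, tG), ord)
    member <- unlist(tab$genes$tags, use.names = FALSE)
    expect_identical(anyDuplicated(member), 0L)
  }
})

test_that("per-gene counts are member-tag sums with conservation", {
  tA <- mktag("A"); tC <- mktag("C")
  db <- mkindex("d1", setNames(list("x1", "x1"), c(tA, tC)))
  tab <- assign_orthologs(c(tA, tC), list(db))
  libs <- list(s1 = mklib(c(tA, tC), c(3, 4), "s1"),
               s2 = mklib(c(tA, tC), c(2, 10), "s2"))
  tab <- gene_counts(tab, libs)
  expect_equal(unname(tab$counts["x1", ]), c(7, 12))
  # conservation: totals over genes equal totals over assigned tags
  for (s in names(libs)) {
    expect_equal(sum(tab$counts[, s]),
                 sum(libs[[s]]$counts[unlist(tab$genes$tags)]))
  }
  expect_equal(unname(tab$tpm["x1", "s1"]), 7 * 1e6 / 7)
  # a library lacking a member tag cannot be aggregated
  expect_error(gene_counts(tab, list(s3 = mklib(tA, 5, "s3"))), "missing")
})

test_that("grouped sums match a groupby oracle on a random fixture", {
  set.seed(35)
  bases <- c("A", "C", "G", "T")
  tags <- unique(replicate(120, paste0(
    "CATG", paste(sample(bases, 17, TRUE), collapse = ""))))
  gene_of <- sample(sprintf("gene%02d", 1:30), length(tags), replace = TRUE)
  db <- mkindex("d1", setNames(as.list(gene_of), tags))
  tab <- assign_orthologs(tags, list(db))
  libs <- list(sA = mklib(tags, sample(2:50, length(tags), TRUE), "sA"),
               sB = mklib(tags, sample(2:50, length(tags), TRUE), "sB"))
  tab <- gene_counts(tab, libs)
  for (s in names(libs)) {
    want <- tapply(as.numeric(libs[[s]]$counts[tags]), gene_of, sum)
    expect_equal(tab$counts[names(want), s], want[names(want)],
                 ignore_attr = TRUE)
  }
})

test_that("planted orthologs with unique tags are recovered exactly", {
  set.seed(36)
  cfg <- synthetic_config(n_genes = 60, divergence = 0, library_depth = 5e4,
                          de_fraction = 0, singleton_noise_rate = 0, seed = 99)
  study <- simulate_study(cfg, annotation = FALSE)
  idx <- lapply(cfg$species, function(sp)
    build_tag_index(study$transcriptomes[[sp]], sp))
  names(idx) <- cfg$species
  clean <- lapply(study$libraries, clean_tags)
  cm <- common_tags(clean)
  tab <- assign_orthologs(cm, idx)
  # zero divergence: every assigned gene is a real planted ortholog from the
  # primary database, and genes with an observed common tag are recovered
  expect_true(all(tab$genes$source_db == cfg$species[1]))
  planted <- study$orthology[[cfg$species[1]]]
  expect_true(all(tab$genes$gene_id %in% planted))
  expect_gt(nrow(tab$genes), 0.9 * cfg$n_genes)
})
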