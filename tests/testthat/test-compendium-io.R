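test_that("pathway tables parse, deduplicate and reject empty records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway\tsource\tgene",
               "P1\tdbA\tG1", "P1\tdbA\tG2", "P1\tdbA\tG1",  # duplicate row
               "P2\tdbA\tG2", "P2\tdbB\tG3"), f)
  pw <- read_pathway_table(f, dialect = "long")
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$genes[[which(pw$pathway_label == "P1")]], c("G1", "G2"))
  # same label in two databases stays two records
  expect_equal(sum(pw$pathway_label == "P2"), 2L)

  # idempotent dedup: duplicated rows change nothing
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway\tsource\tgene", "P1\tdbA\tG1", "P1\tdbA\tG2"), f2)
  expect_identical(read_pathway_table(f2)$genes,
                   pw$genes[pw$pathway_label == "P1"])

  # missing column named in the error; empty gene set warned and dropped
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway\tgene", "P1\tG1"), f3)
  expect_error(read_pathway_table(f3), "source")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway\tsource\tgene", "P1\tdbA\tG1", "P2\tdbA\t"), f4)
  expect_warning(pw4 <- read_pathway_table(f4), "empty gene set")
  expect_equal(pw4$pathway_label, "P1")
})

test_that("GMT dialect parses one record per row", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("P1\tdbA\tG1\tG2\tG2", "P2\tdbA\tG3"), f)
  pw <- read_pathway_table(f, dialect = "gmt")
  expect_equal(pw$n_genes, c(2L, 1L))
  pw2 <- read_pathway_table(f, dialect = "gmt", source_db = "dbX")
  expect_equal(unique(pw2$source_db), "dbX")
})

test_that("SIF ingestion maps relations and drops self loops with a count", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "A\tmystery\tC", "B\tactivates\tB",
               "C\tpp\tD\tE"), f)  # multi-target line -> 2 records
  rec <- read_interactions(f, "db1", dialect = "sif")
  expect_equal(nrow(rec), 4L)
  expect_equal(attr(rec, "load_report")$n_self_loops_dropped, 1L)
  pp <- rec[rec$gene_a == "A" & rec$gene_b == "B", ]
  expect_equal(unname(unlist(pp[, c("direction", "sign", "mechanism")])),
               c("undirected", "unsigned", "direct"))
  # unknown relation string preserved, mapped to the unknown triple
  unk <- rec[rec$raw_relation == "mystery", ]
  expect_equal(unname(unlist(unk[, c("direction", "sign", "mechanism")])),
               c("undirected", "unsigned", "unknown"))
  expect_equal(sum(rec$gene_a == "C"), 2L)

  f2 <- withr::local_tempfile(fileext = ".sif")
  writeLines("A\tpp", f2)
  expect_error(read_interactions(f2, "db1", dialect = "sif"), "target")
})

test_that("annotated TSV dialect honours a relation map and flags blanks", {
  rmap <- data.frame(relation = "activates", direction = "forward",
                     sign = "positive", mechanism = "direct",
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\trelation", "A\tB\tactivates"), f)
  rec <- read_interactions(f, "db1", dialect = "tsv", relation_map = rmap)
  expect_equal(unname(unlist(rec[1, c("direction", "sign", "mechanism")])),
               c("forward", "positive", "direct"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b", "A\t"), f2)
  expect_error(read_interactions(f2, "db1", dialect = "tsv"), "blank")
})

test_that("complex expansion yields all n(n-1)/2 pairs", {
  for (n in 2:6) {
    rec <- expand_complex(paste0("M", seq_len(n)), "db1")
    expect_equal(nrow(rec), choose(n, 2))
    expect_true(all(rec$direction == "undirected"))
    expect_true(all(rec$mechanism == "direct"))
  }
  expect_warning(rec1 <- expand_complex("M1", "db1"), "fewer than 2")
  expect_equal(nrow(rec1), 0L)
})

test_that("build_ensemble filters to the master list and unions provenance", {
  pw <- pathway_table("P1", "pdb", list(c("A", "B")))
  # A-X filtered out: X not on the master list
  comp <- build_ensemble(pw, raw_records(c("A", "A"), c("B", "X"), "db1"))
  expect_equal(nrow(comp$genes), 2L)
  expect_equal(nrow(comp$edges), 1L)
  expect_equal(comp$load_report$per_source$db1$n_outside_master_dropped, 1L)

  # same pair from 3 sources: one canonical edge of weight 3
  recs <- lapply(paste0("db", 1:3), function(s) raw_records("B", "A", s))
  comp3 <- build_ensemble(pw, recs)
  expect_equal(nrow(comp3$edges), 1L)
  expect_equal(comp3$edges$edge_weight, 3L)
  expect_equal(comp3$edges$gene_a, "A")  # canonical order
  # direction flipped with the canonicalization
  expect_true(all(comp3$annotations$direction == "reverse"))

  # per-source totals >= canonical edges, equality iff all weights 1
  gen <- quick_synthetic(31, n_genes = 80, n_edges = 120)
  per_source <- sum(vapply(gen$compendium$interaction_sources, function(s) {
    nrow(edges_for_source(gen$compendium, s))
  }, numeric(1)))
  expect_gte(per_source, nrow(gen$compendium$edges))
  expect_equal(per_source == nrow(gen$compendium$edges),
               all(gen$compendium$edges$edge_weight == 1L))
})

test_that("master-list filtering is monotone in the gene list", {
  recs <- raw_records(c("A", "A", "B", "C"), c("B", "X", "X", "D"), "db1")
  kept <- function(genes) {
    nrow(build_ensemble(pathway_table("P1", "pdb", list(genes)),
                        recs)$edges)
  }
  small <- c("A", "B", "C", "D")
  expect_gte(kept(c(small, "X")), kept(small))
  expect_equal(kept(c(small, "X")), 4L)
})

test_that("id_map applies verbatim, warns on collisions and pass-throughs", {
  pw <- pathway_table("P1", "pdb", list(c("A", "B", "Bold")))
  idm <- data.frame(from = c("Aold", "Bold"), to = c("A", "B"),
                    stringsAsFactors = FALSE)
  expect_warning(
    comp <- build_ensemble(pw, raw_records("Aold", "B", "db1"), id_map = idm),
    "passed through")
  expect_equal(comp$edges$gene_a, "A")
  # Bold in the pathway maps onto B: master list merges the two
  expect_equal(comp$genes$gene_id, c("A", "B"))
  idm2 <- data.frame(from = c("X", "Y"), to = c("Z", "Z"),
                     stringsAsFactors = FALSE)
  expect_warning(build_ensemble(pw, raw_records("A", "B", "db1"),
                                id_map = idm2), "merges")
})

test_that("write/read round-trips exactly and write/read/write is byte-identical", {
  gen <- quick_synthetic(7, n_genes = 100, n_edges = 200,
                         n_meta_datasets = 4L)
  comp <- gen$compendium
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_compendium(comp, d1)
  back <- read_compendium(d1)
  expect_identical(back$genes, comp$genes)
  expect_identical(back$edges, comp$edges)
  expect_identical(back$annotations, comp$annotations)
  expect_identical(back$pathways$genes, comp$pathways$genes)
  expect_identical(back$interaction_sources, comp$interaction_sources)
  write_compendium(back, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = paste("bytes of", f))
  }
})

test_that("empty and single-edge compendia export valid files", {
  pw <- pathway_table("P1", "pdb", list(c("A", "B")))
  empty <- build_ensemble(pw, raw_records("A", "X", "db1"))  # X filtered
  d <- withr::local_tempdir()
  write_compendium(empty, d)
  expect_length(readLines(file.path(d, "edges.sif")), 0L)
  expect_identical(read_compendium(d)$edges, empty$edges)
  one <- build_ensemble(pw, raw_records("A", "B", "db1"))
  d2 <- withr::local_tempdir()
  write_compendium(one, d2)
  expect_length(readLines(file.path(d2, "edges.sif")), 1L)
})

test_that("compendium invariants are enforced", {
  gen <- quick_synthetic(12, n_genes = 60, n_edges = 100)
  comp <- gen$compendium
  expect_silent(validate_compendium(comp))
  broken <- comp
  broken$edges$edge_weight[1] <- broken$edges$edge_weight[1] + 1L
  expect_error(validate_compendium(broken), "edge_weight")
  broken2 <- comp
  broken2$genes$pathway_maps[1] <- broken2$genes$pathway_maps[1] + 1L
  expect_error(validate_compendium(broken2), "pathway_maps")
})
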