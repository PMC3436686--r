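test_that("pathway connectivity decomposes endpoint counts", {
  edges <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                      stringsAsFactors = FALSE)
  pc <- pathway_connectivity(c("A", "B"), edges)
  expect_equal(pc[c("p_t", "p_in", "p_ex")], list(p_t = 3L, p_in = 2L,
                                                  p_ex = 1L))
  expect_equal(pc$ratio, 2 / 3)
  # pathway covering every gene: ratio 1; no internal edges: ratio 0
  expect_equal(pathway_connectivity(c("A", "B", "C"), edges)$ratio, 1)
  expect_equal(pathway_connectivity(c("B", "C"), edges)$ratio, 0)
  # no member gene touched: flagged undefined
  expect_true(is.na(pathway_connectivity(c("X", "Y"), edges)$ratio))
  # P_T = P_IN + P_EX on random synthetic pathways
  gen <- quick_synthetic(33, n_genes = 100, n_edges = 200)
  for (i in seq_len(nrow(gen$compendium$pathways))) {
    pc <- pathway_connectivity(gen$compendium$pathways$genes[[i]],
                               gen$compendium$edges)
    expect_equal(pc$p_t, pc$p_in + pc$p_ex)
    expect_equal(pc$p_in %% 2L, 0L)
  }
})

test_that("membership randomization preserves margins bit-exactly", {
  gen <- quick_synthetic(34, n_genes = 150, n_edges = 200)
  pw <- gen$compendium$pathways
  rnd <- randomize_memberships(pw, seed = 1)
  expect_identical(rnd$n_genes, pw$n_genes)                 # sizes
  maps <- function(p) sort(table(unlist(p$genes)))
  expect_identical(maps(rnd), maps(pw))                     # per-gene counts
  # no duplicate membership within a pathway (pathway_table guarantees sets;
  # verify sizes survived the swap stream)
  expect_identical(vapply(rnd$genes, anyDuplicated, integer(1)),
                   rep(0L, nrow(rnd)))
  # mixing: the incidence structure actually moved
  expect_gt(attr(rnd, "n_swapped"), 0L)
  same <- mapply(function(a, b) length(intersect(a, b)) / length(a),
                 rnd$genes, pw$genes)
  expect_lt(mean(same), 1)
  # determinism under an explicit seed
  expect_identical(randomize_memberships(pw, seed = 9),
                   randomize_memberships(pw, seed = 9))
  # single pathway: no degrees of freedom
  one <- pw[1, , drop = FALSE]
  expect_identical(randomize_memberships(one, seed = 2)$genes, one$genes)
})

test_that("modularity formula hits its calibration points", {
  res <- data.frame(observed_ratio = c(0.2, 0.4), expected_ratio = c(0.2, 0.2))
  m <- res$observed_ratio / res$expected_ratio - 1
  expect_equal(m, c(0, 1))  # random -> 0, two-fold internal -> 1
  # a pathway that owns the whole network: randomization cannot move it
  pw <- pathway_table("P1", "pdb", list(c("A", "B", "C")))
  comp <- build_ensemble(pw, raw_records(c("A", "B"), c("B", "C"), "db1"))
  res1 <- modularity_scores(comp, n_randomizations = 10, seed = 1)
  expect_equal(res1$observed_ratio, 1)
  expect_equal(res1$expected_ratio, 1)
  expect_equal(res1$m, 0)
})

test_that("modularity is computed per pathway against shared randomizations", {
  gen <- quick_synthetic(36, n_genes = 150, n_edges = 300)
  res <- modularity_scores(gen$compendium, n_randomizations = 30, seed = 3)
  expect_s3_class(res, "modularity_result")
  expect_equal(nrow(res), nrow(gen$compendium$pathways))
  expect_true(all(res$observed_ratio >= 0 & res$observed_ratio <= 1,
                  na.rm = TRUE))
  one <- modularity_score(gen$compendium,
                          res$pathway_label[3], res$source_db[3],
                          n_randomizations = 30, seed = 3)
  expect_equal(one$m, res$m[3])
  # pooled expectation variant returns one common expected ratio
  pooled <- modularity_scores(gen$compendium, n_randomizations = 10,
                              seed = 2, pooled = TRUE)
  expect_equal(length(unique(pooled$expected_ratio)), 1L)
})

test_that("mann-whitney matches enumeration, wilcox.test and edge cases", {
  # exhaustive-enumeration oracle at n = 4 vs 4 (70 arrangements)
  x <- c(1.2, 3.4, 5.1, 2.2); y <- c(0.5, 1.9, 2.0, 0.7)
  for (alt in c("greater", "less", "two.sided")) {
    expect_equal(mann_whitney_u(x, y, alt)$p, oracle_mwu_exact(x, y, alt))
  }
  # agreement with wilcox.test exact p on tie-free samples
  set.seed(61)
  for (k in 1:20) {
    a <- runif(sample(3:5, 1)); b <- runif(sample(3:5, 1))
    got <- mann_whitney_u(a, b, "greater")
    ref <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  # ties handled by enumeration too
  xt <- c(1, 2, 2, 3); yt <- c(2, 2, 1, 1)
  expect_equal(mann_whitney_u(xt, yt, "greater")$p,
               oracle_mwu_exact(xt, yt, "greater"))
  # identical samples: p = 1; separation: p < 0.001 one-sided at n = 50
  expect_equal(mann_whitney_u(rep(2, 5), rep(2, 6))$p, 1)
  expect_gte(mann_whitney_u(c(1, 2), c(1, 2), "greater")$p, 0.5)
  set.seed(8)
  expect_lt(mann_whitney_u(rnorm(50, 2), rnorm(50), "greater")$p, 1e-3)
  # large-sample normal approximation tracks wilcox.test
  xl <- rnorm(40); yl <- rnorm(35, 0.3)
  expect_equal(mann_whitney_u(xl, yl, "two.sided")$p,
               stats::wilcox.test(xl, yl, exact = FALSE,
                                  correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("modularity matrix covers sources x pathway dbs with sane cells", {
  cfg <- synthetic_config(n_genes = 150,
                          pathway_sources = c(dbA = 6L, dbB = 6L),
                          n_edges_per_source = 300,
                          internal_edge_enrichment = 2, seed = 38)
  gen <- generate_compendium(cfg)
  mm <- modularity_matrix(gen$compendium, n_randomizations = 25, seed = 5)
  expect_equal(dim(mm$m), c(4L, 2L))  # 3 sources + Ensemble, 2 pathway dbs
  expect_equal(rownames(mm$m)[4], "Ensemble")
  expect_true(all(mm$p >= 0 & mm$p <= 1, na.rm = TRUE))
  # planted enrichment shows up as significant cells on the ensemble row
  expect_lt(max(mm$p["Ensemble", ]), 0.05)
  # single-source compendium: source row duplicates the ensemble row
  pw <- pathway_table(c("P1", "P2"), "pdb",
                      list(c("A", "B", "C"), c("C", "D", "E")))
  comp1 <- build_ensemble(pw, raw_records(c("A", "B", "C", "D"),
                                          c("B", "C", "D", "E"), "only"))
  mm1 <- modularity_matrix(comp1, n_randomizations = 10, seed = 1)
  expect_equal(dim(mm1$m), c(2L, 1L))
  expect_equal(mm1$m["only", ], mm1$m["Ensemble", ])
})
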