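make_view <- function(from, to, genes = sort(unique(c(from, to)))) {
  pw <- pathway_table("P1", "pdb", list(genes))
  comp <- build_ensemble(pw, raw_records(from, to, "db1",
                                         direction = "forward"))
  directed_view(comp)
}

test_that("directed view applies direction and filter semantics", {
  pw <- pathway_table("P1", "pdb", list(c("A", "B")))
  comp <- build_ensemble(pw, list(
    raw_records("A", "B", "dbU", direction = "undirected"),
    raw_records("A", "B", "dbF", direction = "forward"),
    raw_records("A", "B", "dbR", direction = "reverse")))
  dv <- directed_view(comp)                       # directed only
  expect_equal(nrow(dv$arcs), 2L)                 # both orientations present
  expect_setequal(paste(dv$arcs$from, dv$arcs$to), c("A B", "B A"))
  dv2 <- directed_view(comp, directed_only = FALSE)
  expect_equal(nrow(dv2$arcs), 2L)                # parallel arcs collapse
  undir_only <- build_ensemble(pw, raw_records("A", "B", "dbU",
                                               direction = "undirected"))
  expect_warning(dv3 <- directed_view(undir_only), "empty")
  expect_equal(nrow(dv3$arcs), 0L)
  # source filter
  dvF <- directed_view(comp, sources = "dbF")
  expect_equal(paste(dvF$arcs$from, dvF$arcs$to), "A B")
  # arc count tracks the generator's directed fraction
  gen <- quick_synthetic(44, n_genes = 150, n_edges = 400,
                         directed_fraction = 0.3)
  dvg <- directed_view(gen$compendium)
  n_ann <- nrow(gen$compendium$annotations)
  expect_lt(abs(nrow(dvg$arcs) / n_ann - 0.3), 0.06)
})

test_that("all shortest paths come back sorted and complete", {
  dia <- make_view(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  sp <- shortest_paths_all(dia, "A", "D")
  expect_equal(sp$length, 2L)
  expect_equal(sp$paths, list(c("A", "B", "D"), c("A", "C", "D")))
  direct <- make_view("A", "B")
  expect_equal(shortest_paths_all(direct, "A", "B"),
               list(length = 1L, paths = list(c("A", "B"))))
  apart <- make_view(c("A", "C"), c("B", "D"))
  expect_equal(shortest_paths_all(apart, "A", "D")$length, NA_integer_)
})

test_that("bounded enumeration matches hand examples", {
  chain <- make_view(c("A", "B", "C"), c("B", "C", "D"))
  pe <- enumerate_paths(chain, "A", "D", max_length = 3)
  expect_equal(unname(pe$counts_by_length), c(0, 0, 1))
  g <- make_view(c("A", "A", "B", "B", "C"), c("B", "C", "C", "D", "D"))
  pe2 <- enumerate_paths(g, "A", "D", max_length = 3)
  expect_equal(sum(pe2$counts_by_length), 3)      # A-B-D, A-C-D, A-B-C-D
  expect_equal(unname(pe2$cumulative_counts), c(0, 2, 3))
  expect_false(pe2$truncated)
  # count ceiling flags truncation
  k <- expand.grid(a = paste0("U", 1:4), b = paste0("V", 1:4))
  full <- make_view(c(rep("S", 4), as.character(k$a), paste0("V", 1:4)),
                    c(paste0("U", 1:4), as.character(k$b), rep("T", 4)))
  pe3 <- enumerate_paths(full, "S", "T", max_length = 4, max_paths = 3)
  expect_true(pe3$truncated)
  expect_equal(sum(pe3$counts_by_length), 3)
})

test_that("enumeration and shortest paths match brute force on random digraphs", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(5:12, 1)
    adj <- random_digraph_adj(n, runif(1, 0.15, 0.4))
    ids <- sprintf("N%02d", seq_len(n))
    arcs <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (length(adj[[i]])) data.frame(from = ids[i], to = ids[adj[[i]]])
    }))
    if (is.null(arcs)) next
    view <- make_view(arcs$from, arcs$to, genes = ids)
    s <- 1L; t <- n
    L <- sample(3:8, 1)
    got <- enumerate_paths(view, ids[s], ids[t], max_length = L)
    want <- oracle_count_paths(adj, s, t, L)
    expect_equal(unname(got$counts_by_length), want$counts)
    sp <- oracle_shortest_paths(adj, s, t)
    expect_equal(got$shortest_length,
                 if (is.na(sp$length)) NA_integer_ else sp$length)
    if (!is.na(sp$length)) {
      want_paths <- lapply(sp$paths, function(p) ids[p])
      want_paths <- want_paths[order(vapply(want_paths, paste,
                                            character(1),
                                            collapse = "\r"))]
      expect_equal(got$shortest_paths, want_paths)
    }
  }
})

test_that("through fraction obeys its boundary contracts", {
  chain <- make_view(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(through_fraction(chain, "A", "D", 4, required_node = "B"), 1)
  # required node is the unique out-neighbour of the source
  expect_equal(through_fraction(chain, "A", "D", 4, required_node = "B",
                                position = "first_hop"), 1)
  # source/target count as traversed
  expect_equal(through_fraction(chain, "A", "D", 4, required_node = "A"), 1)
  apart <- make_view(c("A", "C"), c("B", "D"))
  expect_warning(tf <- through_fraction(apart, "A", "D", 4,
                                        required_node = "B"), "no path")
  expect_true(is.na(tf))
})

test_that("planted bypass structure is recovered exactly", {
  cfg <- synthetic_config(
    n_genes = 50, pathway_sources = c(bg = 3L), n_edges_per_source = 80,
    seed = 71,
    scaffold = list(chain = paste0("S", 1:8), n_bypass = 5L,
                    n_intermediates = 3L))
  gen <- generate_scaffold_network(cfg)
  dv <- directed_view(gen$compendium)
  # fraction of length <= 2 routes through node 2 from brute-force listing
  ids <- dv$genes
  adj <- lapply(seq_along(ids), function(i) {
    which(ids %in% dv$arcs$to[dv$arcs$from == ids[i]])
  })
  s <- match("S1", ids); t <- match("S8", ids); q <- match("S2", ids)
  want <- oracle_count_paths(adj, s, t, 2, keep_paths = TRUE)
  through <- vapply(want$paths, function(p) q %in% p, logical(1))
  if (sum(want$counts) > 0) {
    expect_equal(through_fraction(dv, "S1", "S8", 2, required_node = "S2"),
                 mean(through))
  }
  # same check at the full depth against the oracle
  want8 <- oracle_count_paths(adj, s, t, 8, keep_paths = TRUE)
  through8 <- vapply(want8$paths, function(p) q %in% p, logical(1))
  expect_equal(through_fraction(dv, "S1", "S8", 8, required_node = "S2"),
               mean(through8))
  # planted intermediates recovered exactly, classes included
  se <- expand_scaffold(dv, gen$truth$scaffold_nodes)
  tr <- gen$truth$intermediates[order(gen$truth$intermediates$gene), ]
  expect_equal(attr(se, "n_distinct"), 3L)
  got <- se[match(tr$gene, se$gene), c("gene", "from", "to", "class")]
  rownames(got) <- rownames(tr) <- NULL
  expect_equal(got, tr[, c("gene", "from", "to", "class")],
               ignore_attr = TRUE)
})

test_that("scaffold expansion handles empty and planted cases", {
  chain <- make_view(c("A", "B", "C"), c("B", "C", "D"))
  se <- expand_scaffold(chain, c("A", "B", "C", "D"))
  expect_equal(nrow(se), 0L)
  expect_equal(attr(se, "n_distinct"), 0L)
  # hand-planted intermediate classes
  v <- make_view(c("A", "B", "C", "A", "X", "C", "Y", "B", "Z"),
                 c("B", "C", "D", "X", "B", "Y", "A", "Z", "D"))
  se2 <- expand_scaffold(v, c("A", "B", "C", "D"))
  cls <- setNames(se2$class, se2$gene)
  expect_equal(unname(cls["X"]), "parallel")     # A -> X -> B
  expect_equal(unname(cls["Y"]), "feed-back")    # C -> Y -> A
  expect_equal(unname(cls["Z"]), "feed-forward") # B -> Z -> D
})

test_that("scaffold edge enrichment equals the hypergeometric tail sum", {
  gen <- quick_synthetic(73, n_genes = 100, n_edges = 200,
                         source_sharing = 0.3)
  comp <- gen$compendium
  # take an existing path of edges as a pseudo-scaffold
  e <- comp$edges[order(-comp$edges$edge_weight), ][1:4, ]
  chain <- c(e$gene_a[1], e$gene_b[1])
  en <- scaffold_edge_enrichment(comp, chain, high_weight_threshold = 2)
  want <- oracle_hyper_tail(en$n_high_sample, en$n_high_population,
                            en$n_population, 1)
  expect_equal(en$p_value, want, tolerance = 1e-12)
  # all edges high weight: p = 1
  en1 <- scaffold_edge_enrichment(comp, chain, high_weight_threshold = 1)
  expect_equal(en1$p_value, 1)
  # large-population tail: 7 successes in 7 draws at a 10% success rate
  expect_equal(phyper(6, 6328, 63276 - 6328, 7, lower.tail = FALSE),
               oracle_hyper_tail(7, 6328, 63276, 7), tolerance = 1e-12)
  expect_error(scaffold_edge_enrichment(comp, c("NOPE1", "NOPE2"), 2),
               "missing")
})

test_that("the ligand pipeline runs identically across sentinel queries", {
  queries <- list(c("EGF", "MAPK3"), c("TGFB1", "SMAD4"),
                  c("TNF", "NFKB1"), c("WNT1", "GSK3B"))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    chain <- c(q[1], paste0("M", i, "_", 1:3), q[2])
    cfg <- synthetic_config(
      n_genes = 40, pathway_sources = c(bg = 2L), n_edges_per_source = 60,
      seed = 80 + i,
      scaffold = list(chain = chain, n_bypass = 2L, n_intermediates = 2L))
    gen <- generate_scaffold_network(cfg)
    dv <- directed_view(gen$compendium)
    pe <- enumerate_paths(dv, q[1], q[2], max_length = 6,
                          required_node = chain[2])
    expect_s3_class(pe, "path_enumeration")
    expect_gte(sum(pe$counts_by_length), 1)
    expect_true(!is.na(pe$through_fraction))
    expect_true(all(diff(pe$cumulative_counts) >= 0))
  }
})
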