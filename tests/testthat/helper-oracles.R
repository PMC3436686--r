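# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately written without reusing the package's
# implementation paths (BFS path counting instead of igraph, recursive
# enumeration instead of the iterative DFS, direct tail sums instead of
# phyper, hclust as the clustering reference).

# ---- graph fixtures ---------------------------------------------------------

# adjacency list (integer) of a random simple digraph on n nodes
random_digraph_adj <- function(n, p) {
  m <- matrix(runif(n * n) < p, n, n)
  diag(m) <- FALSE
  lapply(seq_len(n), function(i) which(m[i, ]))
}

# symmetric random graph as an adjacency matrix
random_ugraph_mat <- function(n, p) {
  m <- matrix(FALSE, n, n)
  up <- upper.tri(m)
  m[up] <- runif(sum(up)) < p
  m <- m | t(m)
  m
}

# raw interaction records data frame from from/to vectors
raw_records <- function(from, to, source_db, direction = "forward",
                        sign = "unsigned", mechanism = "unknown",
                        dataset = NA_character_) {
  data.frame(gene_a = from, gene_b = to, direction = direction,
             sign = sign, mechanism = mechanism,
             raw_relation = NA_character_, dataset = dataset,
             source_db = source_db, stringsAsFactors = FALSE)
}

# one-pathway compendium over explicit undirected edges
tiny_compendium <- function(edge_from, edge_to,
                            genes = sort(unique(c(edge_from, edge_to))),
                            source_db = "db1", direction = "undirected") {
  pw <- pathway_table("P1", "pdb", list(genes))
  build_ensemble(pw, raw_records(edge_from, edge_to, source_db,
                                 direction = direction))
}

# small fully random synthetic compendium, convenient defaults
quick_synthetic <- function(seed, n_genes = 120L, n_edges = 250L,
                            enrichment = 1, mode = "fold_vs_null", ...) {
  cfg <- synthetic_config(n_genes = n_genes,
                          pathway_sources = c(dbA = 4L, dbB = 4L),
                          n_edges_per_source = n_edges,
                          internal_edge_enrichment = enrichment,
                          enrichment_mode = mode, seed = seed, ...)
  generate_compendium(cfg)
}

# ---- betweenness oracle -----------------------------------------------------

# all-pairs BFS path counting on an undirected adjacency matrix; endpoints
# excluded; pair-normalized so values are fractions
oracle_betweenness_norm <- function(adj) {
  n <- nrow(adj)
  oracle_betweenness_raw(adj) / ((n - 1) * (n - 2) / 2)
}

oracle_betweenness_raw <- function(adj) {
  n <- nrow(adj)
  dmat <- matrix(Inf, n, n)
  smat <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- rep(0, n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s; lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ])) {
          if (!is.finite(d[u])) {
            d[u] <- lev; nxt <- c(nxt, u); sg[u] <- sg[u] + sg[v]
          } else if (d[u] == lev) {
            sg[u] <- sg[u] + sg[v]
          }
        }
      }
      frontier <- unique(nxt)
    }
    dmat[s, ] <- d; smat[s, ] <- sg
  }
  bt <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      if (!is.finite(dmat[s, t])) next
      v <- setdiff(which(dmat[s, ] + dmat[t, ] == dmat[s, t]), c(s, t))
      if (length(v)) bt[v] <- bt[v] + smat[s, v] * smat[t, v] / smat[s, t]
    }
  }
  bt
}

# ---- path enumeration oracles -----------------------------------------------

# recursive exhaustive enumeration of simple paths; returns exact-length
# counts (and optionally the node sequences)
oracle_count_paths <- function(adj, s, t, max_length, keep_paths = FALSE) {
  counts <- numeric(max_length)
  paths <- list()
  visit <- function(v, depth, used) {
    for (u in adj[[v]]) {
      if (u == t) {
        counts[depth + 1] <<- counts[depth + 1] + 1
        if (keep_paths) paths[[length(paths) + 1]] <<- c(used, t)
        next
      }
      if (depth + 1 < max_length && !(u %in% used)) {
        visit(u, depth + 1, c(used, u))
      }
    }
  }
  if (s != t) visit(s, 0L, s)
  list(counts = counts, paths = paths)
}

oracle_shortest_paths <- function(adj, s, t, max_length = length(adj)) {
  res <- oracle_count_paths(adj, s, t, max_length, keep_paths = TRUE)
  if (!length(res$paths)) return(list(length = NA_integer_, paths = list()))
  lens <- vapply(res$paths, length, integer(1)) - 1L
  keep <- res$paths[lens == min(lens)]
  list(length = min(lens), paths = keep)
}

# ---- small-probability oracles ----------------------------------------------

# upper-tail hypergeometric probability by direct density summation
oracle_hyper_tail <- function(obs, n_succ, n_pop, k) {
  sum(dhyper(obs:min(k, n_succ), n_succ, n_pop - n_succ, k))
}

# full-arrangement Mann-Whitney enumeration (one-sided, x greater)
oracle_mwu_exact <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  us <- apply(combn(length(pooled), n1), 2, u_of)
  switch(alternative,
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs),
         two.sided = min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs))))
}

# exact expectation of the Jaccard index of two uniform random subsets of
# fixed sizes a, b from a universe of size u
oracle_expected_jaccard <- function(u, a, b) {
  n <- max(0, a + b - u):min(a, b)
  sum(dhyper(n, a, u - a, b) * n / (a + b - n))
}

# ---- supplementary-data hook ------------------------------------------------

# The paper-number reproduction criteria need the study's supplementary
# tables (pathway list, gene annotations, edge annotations, pathway gene
# sets). They are not distributed with this package; a user who obtains them
# can drop them here to activate those checks.
load_supplementary_compendium <- function() {
  dir <- system.file("extdata", "supplementary", package = "pkncompendium")
  files <- c("pathways.tsv", "gene_annotations.tsv")
  if (dir == "" || !all(file.exists(file.path(dir, files)))) {
    stop("supplementary tables (pathway list, gene/edge annotations) are not ",
         "distributed with this package; place them under ",
         "inst/extdata/supplementary/ to run the paper-number reproduction ",
         "checks", call. = FALSE)
  }
  pw <- read_pathway_table(file.path(dir, "pathways.tsv"), dialect = "long")
  inter <- lapply(list.files(dir, pattern = "^interactions_.*\\.tsv$",
                             full.names = TRUE), function(f) {
    read_interactions(f, sub("^interactions_(.*)\\.tsv$", "\\1", basename(f)),
                      dialect = "tsv")
  })
  ga <- read.delim(file.path(dir, "gene_annotations.tsv"),
                   stringsAsFactors = FALSE)
  build_ensemble(pw, inter, gene_annotations = ga)
}
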