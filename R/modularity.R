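#' Pathway connectivity decomposition
#'
#' `P_T` is the sum of the degrees of the pathway's member genes restricted
#' to the given network. It decomposes into `P_IN` (each internal edge --
#' both endpoints inside the pathway -- contributes both endpoints, i.e. 2)
#' and `P_EX` (each external edge -- exactly one endpoint inside --
#' contributes 1), so `P_T = P_IN + P_EX` holds exactly.
#'
#' @param genes character vector: the pathway's member genes.
#' @param edges data frame of canonical pairs (`gene_a`, `gene_b`).
#' @return List with `p_t`, `p_in`, `p_ex` and `ratio` (`P_IN/P_T`; `NA`,
#'   flagged undefined, when no member gene has any edge).
#' @export
pathway_connectivity <- function(genes, edges) {
  ina <- edges$gene_a %in% genes
  inb <- edges$gene_b %in% genes
  p_in <- 2L * sum(ina & inb)
  p_ex <- sum(xor(ina, inb))
  p_t <- p_in + p_ex
  list(p_t = p_t, p_in = p_in, p_ex = p_ex,
       ratio = if (p_t > 0) p_in / p_t else NA_real_)
}

incidence_from_pathways <- function(pathways, gene_ids) {
  n <- vapply(pathways$genes, length, integer(1))
  list(pathway = rep(seq_len(nrow(pathways)), n),
       gene = match(unlist(pathways$genes), gene_ids))
}

pathways_from_incidence <- function(inc, pathways, gene_ids) {
  genes <- split(gene_ids[inc$gene], factor(inc$pathway,
                                            levels = seq_len(nrow(pathways))))
  pathway_table(pathways$pathway_label, pathways$source_db, genes)
}

#' Randomize pathway memberships preserving all margins
#'
#' Shuffles the gene-pathway bipartite incidence structure by repeated
#' random pairwise membership swaps. Every gene's Pathway Maps and every
#' pathway's size are preserved exactly, and no pathway acquires a duplicate
#' member. This is the null model behind the pathway modularity score.
#'
#' @param pathways a [pathway_table()].
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @param n_swaps number of swap attempts; default 10 times the number of
#'   incidences.
#' @return A randomized `pathway_table`; attribute `"n_swapped"` counts the
#'   successful swaps (a diagnostic: 0 successful swaps on a table with
#'   swappable incidences indicates an infeasible budget).
#' @export
randomize_memberships <- function(pathways, seed = NULL, n_swaps = NULL) {
  run <- function() {
    gene_ids <- sort(unique(unlist(pathways$genes)))
    inc <- incidence_from_pathways(pathways, gene_ids)
    n_swaps <- n_swaps %||% (10L * length(inc$gene))
    res <- swap_incidences(inc$pathway, inc$gene, nrow(pathways),
                           length(gene_ids), as.integer(n_swaps))
    out <- pathways_from_incidence(list(pathway = res$pathway,
                                        gene = res$gene),
                                   pathways, gene_ids)
    attr(out, "n_swapped") <- res$n_swapped
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

ratio_matrix <- function(memb, ea_idx, eb_idx) {
  internal <- memb[, ea_idx, drop = FALSE] & memb[, eb_idx, drop = FALSE]
  p_in <- 2 * rowSums(internal)
  external <- xor(memb[, ea_idx, drop = FALSE], memb[, eb_idx, drop = FALSE])
  p_t <- p_in + rowSums(external)
  ifelse(p_t > 0, p_in / p_t, NA_real_)
}

# Shared machinery: observed and expected internal fractions for every
# pathway of a table against one edge set, with n_randomizations
# membership-randomized replicates of the WHOLE table.
modularity_engine <- function(pathways, edges, n_randomizations, seed,
                              n_swaps = NULL, pooled = FALSE) {
  # universe covers edge endpoints outside this pathway collection: they
  # still carry external-degree mass for P_T
  gene_ids <- sort(unique(c(unlist(pathways$genes),
                            edges$gene_a, edges$gene_b)))
  ea <- match(edges$gene_a, gene_ids)
  eb <- match(edges$gene_b, gene_ids)
  memb <- membership_matrix(pathways, gene_ids)
  observed <- ratio_matrix(memb, ea, eb)
  inc <- incidence_from_pathways(pathways, gene_ids)
  n_swaps <- n_swaps %||% (10L * length(inc$gene))
  run <- function() {
    exp_mat <- matrix(NA_real_, n_randomizations, nrow(pathways))
    pooled_ratio <- numeric(n_randomizations)
    for (r in seq_len(n_randomizations)) {
      rr <- swap_incidences(inc$pathway, inc$gene, nrow(pathways),
                            length(gene_ids), as.integer(n_swaps))
      mr <- matrix(FALSE, nrow(pathways), length(gene_ids))
      mr[cbind(rr$pathway, rr$gene)] <- TRUE
      exp_mat[r, ] <- ratio_matrix(mr, ea, eb)
    }
    exp_mat
  }
  exp_mat <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  expected <- if (pooled) {
    rep(mean(exp_mat, na.rm = TRUE), nrow(pathways))
  } else {
    colMeans(exp_mat, na.rm = TRUE)
  }
  data.frame(
    pathway_label = pathways$pathway_label,
    source_db = pathways$source_db,
    observed_ratio = observed,
    expected_ratio = expected,
    m = ifelse(is.na(observed) | is.na(expected) | expected == 0,
               NA_real_, observed / expected - 1),
    n_randomizations = n_randomizations,
    stringsAsFactors = FALSE
  )
}

#' Pathway modularity scores against the randomization null
#'
#' For each pathway record, compares the observed internal-edge fraction
#' `P_IN/P_T` with its expectation `E_IN/E_T` under `n_randomizations`
#' membership randomizations of the whole table (gene multiplicities and
#' pathway sizes preserved). The modularity score is
#' `M = (P_IN/P_T) / (E_IN/E_T) - 1`: 0 for a random distribution of edges,
#' 1 for two-fold more internal edges than expected by chance.
#'
#' @param pathways a [pathway_table()] or a `compendium` (whose pathway
#'   table is used).
#' @param edges canonical edge data frame; defaults to the compendium's full
#'   ensemble edge table when `pathways` is a compendium.
#' @param n_randomizations number of whole-table randomizations (default
#'   100).
#' @param seed optional seed for the randomization stream.
#' @param pooled if `TRUE`, the expected ratio is pooled across pathways per
#'   randomization instead of per-pathway means.
#' @return A `modularity_result` data frame with one row per pathway:
#'   observed and expected ratios, `m`, and the randomization count. `m` is
#'   `NA` (flagged undefined) when the expected ratio is 0 or the pathway
#'   touches no edge.
#' @export
modularity_scores <- function(pathways, edges = NULL,
                              n_randomizations = 100L, seed = NULL,
                              pooled = FALSE) {
  if (inherits(pathways, "compendium")) {
    edges <- edges %||% pathways$edges
    pathways <- pathways$pathways
  }
  assert_that(!is.null(edges), "an edge table is required")
  out <- modularity_engine(pathways, edges, n_randomizations, seed,
                           pooled = pooled)
  class(out) <- c("modularity_result", "data.frame")
  out
}

#' Modularity score of a single pathway
#'
#' Convenience wrapper around [modularity_scores()]: the expectation still
#' comes from randomizations of the full pathway table, as the null
#' requires.
#'
#' @inheritParams modularity_scores
#' @param pathway_label,source_db identify the pathway record.
#' @return One-row `modularity_result`.
#' @export
modularity_score <- function(pathways, pathway_label, source_db = NULL,
                             edges = NULL, n_randomizations = 100L,
                             seed = NULL) {
  all <- modularity_scores(pathways, edges, n_randomizations, seed)
  i <- all$pathway_label == pathway_label &
    (is.null(source_db) | all$source_db == (source_db %||% all$source_db))
  assert_that(any(i), "pathway '%s' not found", pathway_label)
  all[i, , drop = FALSE]
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. For small samples without
#' excessive cost (`choose(n1 + n2, n1) <= 2e5`) the p-value is computed by
#' exact enumeration of all group assignments of the pooled sample; larger
#' samples use the tie-corrected normal approximation with continuity
#' correction. One-sided "greater" (first sample stochastically larger) is
#' the default, matching the directional modularity claim.
#'
#' @param x,y numeric samples (each of size >= 1).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default chooses by cost.
#' @return List with `u` (U statistic of `x`), `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("greater", "less",
                                                 "two.sided"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) >= 1 && length(y) >= 1,
              "both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  u <- u_of(seq_len(n1))
  if (length(unique(pooled)) == 1L) {
    return(list(u = u, p = 1, method = "degenerate"))
  }
  do_exact <- exact %||% (choose(N, n1) <= 2e5)
  if (do_exact) {
    combos <- combn(N, n1)
    us <- apply(combos, 2L, u_of)
    p <- switch(alternative,
      greater = mean(us >= u),
      less = mean(us <= u),
      two.sided = min(1, 2 * min(mean(us >= u), mean(us <= u)))
    )
    return(list(u = u, p = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- switch(alternative,
    greater = (u - mu - 0.5) / sigma,
    less = (u - mu + 0.5) / sigma,
    two.sided = (u - mu - sign(u - mu) * 0.5) / sigma
  )
  p <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two.sided = 2 * pnorm(abs(z), lower.tail = FALSE)
  )
  list(u = u, p = min(1, p), method = "normal")
}

#' Modularity matrix over pathway databases x interaction networks
#'
#' For every pathway source database (columns) and every interaction network
#' (rows: each interaction source plus the full Ensemble), computes the
#' per-pathway modularity scores, the cell mean M, and a Mann-Whitney
#' p-value comparing the per-pathway observed-ratio distribution against the
#' per-pathway expected-ratio distribution (one-sided, observed greater).
#' Randomizations of each pathway database's table are shared across the
#' network rows.
#'
#' @param compendium a `compendium`.
#' @param n_randomizations randomizations per pathway database.
#' @param seed optional seed.
#' @param alternative sidedness of the Mann-Whitney test.
#' @return A `modularity_matrix`: list with `m` (mean-M matrix), `p`
#'   (p-value matrix), `per_pathway` (list of `modularity_result` by cell),
#'   `row_order` and `col_order` (deterministic average-linkage orders).
#'   Cells where no pathway gene touches the network are `NA` (flagged
#'   missing).
#' @export
modularity_matrix <- function(compendium, n_randomizations = 100L,
                              seed = NULL,
                              alternative = "greater") {
  nets <- c(compendium$interaction_sources, "Ensemble")
  pdbs <- compendium$pathway_sources
  m <- p <- matrix(NA_real_, length(nets), length(pdbs),
                   dimnames = list(nets, pdbs))
  per <- list()
  seeds <- if (is.null(seed)) rep(list(NULL), length(pdbs)) else
    as.list(seed + seq_along(pdbs))
  for (ci in seq_along(pdbs)) {
    pws <- compendium$pathways[compendium$pathways$source_db == pdbs[ci], ,
                               drop = FALSE]
    for (ri in seq_along(nets)) {
      edges <- edges_for_source(compendium, nets[ri])
      res <- modularity_engine(pws, edges, n_randomizations, seeds[[ci]])
      per[[paste(nets[ri], pdbs[ci], sep = "|")]] <- res
      ok <- !is.na(res$m)
      if (any(ok)) {
        m[ri, ci] <- mean(res$m[ok])
        both <- !is.na(res$observed_ratio) & !is.na(res$expected_ratio)
        p[ri, ci] <- mann_whitney_u(res$observed_ratio[both],
                                    res$expected_ratio[both],
                                    alternative = alternative)$p
      }
    }
  }
  impute <- function(v) { v[is.na(v)] <- mean(v, na.rm = TRUE); v }
  out <- list(m = m, p = p, per_pathway = per,
              row_order = cluster_order(as.matrix(dist(impute(m)))),
              col_order = cluster_order(as.matrix(dist(t(impute(m))))))
  class(out) <- "modularity_matrix"
  out
}
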