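comp_igraph <- function(compendium, directed = FALSE) {
  igraph::graph_from_data_frame(
    compendium$edges[, c("gene_a", "gene_b")],
    directed = directed,
    vertices = compendium$genes$gene_id
  )
}

#' Per-gene degree and network summary
#'
#' Degree counts distinct canonical edges incident to each gene. Two mean
#' degree conventions are reported: `mean_degree_paper` is edges/nodes (the
#' convention under which the real compendium's density reads 26.8) and
#' `mean_degree_graph` is the usual 2 x edges/nodes.
#'
#' @param compendium a `compendium`.
#' @return List with `degree` (named integer vector) and `summary`
#'   (`n_nodes`, `n_edges`, `mean_degree_paper`, `mean_degree_graph`).
#' @export
compute_degrees <- function(compendium) {
  g <- compendium$genes$gene_id
  deg <- tabulate(match(c(compendium$edges$gene_a, compendium$edges$gene_b),
                        g), length(g))
  n_nodes <- length(g)
  n_edges <- nrow(compendium$edges)
  list(
    degree = setNames(as.integer(deg), g),
    summary = list(
      n_nodes = n_nodes,
      n_edges = n_edges,
      mean_degree_paper = n_edges / n_nodes,
      mean_degree_graph = 2 * n_edges / n_nodes
    )
  )
}

#' Betweenness centrality as a fraction
#'
#' Computed on the undirected projection with unit edge lengths, endpoints
#' excluded, normalized by the number of vertex pairs so that values are
#' fractions in \[0, 1\] (a middle node on a 3-node path scores 1).
#'
#' @param compendium a `compendium`.
#' @return Named numeric vector over all genes.
#' @export
compute_betweenness <- function(compendium) {
  g <- comp_igraph(compendium, directed = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(b), igraph::V(g)$name)[compendium$genes$gene_id]
}

#' Pathway Maps: per-gene pathway multiplicity
#'
#' The number of database-scoped pathway records containing each gene.
#' Pathways with similar labels in different databases are never merged, so
#' a gene in "EGFR1 signalling" (one database) and "EGF receptor signalling"
#' (another) counts 2.
#'
#' @param compendium a `compendium`.
#' @return Named integer vector over all genes.
#' @export
compute_pathway_maps <- function(compendium) {
  g <- compendium$genes$gene_id
  tab <- table(factor(unlist(compendium$pathways$genes), levels = g))
  setNames(as.integer(tab), g)
}

#' Hypergeometric Z-score
#'
#' `Z = (r - nR/N) / sqrt(n (R/N)(1 - R/N)(N - n)/(N - 1))`: the number of
#' category members `r` observed in a sample of size `n`, standardized by
#' the hypergeometric mean and standard deviation for a population of `N`
#' elements of which `R` are in the category. When the standard deviation is
#' zero (`n = N`, or `R` in `{0, N}`) the sample is forced to its
#' expectation and Z is defined as 0. `|Z| > 2` corresponds approximately to
#' p < 0.05.
#'
#' @param N population size (> 1).
#' @param R number of positive elements in the population.
#' @param n sample size.
#' @param r number of positive elements in the sample.
#' @return Numeric Z-score (vectorized over the arguments).
#' @export
hypergeometric_z <- function(N, R, n, r) {
  assert_that(all(N > 1), "N must exceed 1")
  assert_that(all(R >= 0 & R <= N), "R must satisfy 0 <= R <= N")
  assert_that(all(n > 0 & n <= N), "n must satisfy 0 < n <= N")
  assert_that(all(r >= 0 & r <= pmin(n, R)), "r must satisfy 0 <= r <= min(n, R)")
  p <- R / N
  v <- n * p * (1 - p) * (N - n) / (N - 1)
  z <- ifelse(v > 0, (r - n * p) / sqrt(v), 0)
  as.numeric(z)
}

region_score <- function(region, maps, bt, n) {
  pm <- rank(maps, ties.method = "average") / n
  pb <- rank(bt, ties.method = "average") / n
  switch(region,
    maps_hi_bt_hi = pm * pb,
    maps_lo_bt_hi = (1 - pm) * pb,
    maps_lo_bt_lo = (1 - pm) * (1 - pb),
    maps_hi_bt_lo = pm * (1 - pb),
    stop_format("unknown region '%s'", region)
  )
}

#' Sliding-window functional enrichment scan
#'
#' Ranks genes toward the tip of a topological region of the Pathway Maps
#' vs. betweenness landscape, then computes the hypergeometric Z-score of a
#' function category in successively widening sample windows: starting from
#' the 10 genes at the tip and widening to the whole network. The tip score
#' is the product of the percentile ranks of Pathway Maps and betweenness in
#' the region's preferred directions, with ties broken by gene id.
#'
#' @param compendium a `compendium`; betweenness is computed on demand if
#'   not cached in the gene table.
#' @param region one of `"maps_hi_bt_hi"`, `"maps_lo_bt_hi"`,
#'   `"maps_lo_bt_lo"`, `"maps_hi_bt_lo"`.
#' @param category a function category present in the gene table.
#' @param n_windows optional decimation of the window schedule (default:
#'   every integer sample size from 10 to N).
#' @return An `enrichment_scan` data frame with columns `window_n`,
#'   `window_fraction`, `r`, `z`.
#' @export
enrichment_scan <- function(compendium, region, category, n_windows = NULL) {
  genes <- compendium$genes
  assert_that(category %in% genes$function_category,
              "category '%s' absent from the gene annotation table", category)
  bt <- genes$betweenness
  if (all(is.na(bt))) bt <- compute_betweenness(compendium)
  N <- nrow(genes)
  score <- region_score(region, genes$pathway_maps, bt, N)
  ord <- order(-score, genes$gene_id)
  hit <- genes$function_category[ord] == category
  R <- sum(hit)
  ns <- decimate_windows(min(10L, N), N, n_windows)
  r <- cumsum(hit)[ns]
  out <- data.frame(window_n = ns, window_fraction = ns / N, r = r,
                    z = hypergeometric_z(N, R, ns, r))
  attr(out, "region") <- region
  attr(out, "category") <- category
  attr(out, "ranked_genes") <- genes$gene_id[ord]
  class(out) <- c("enrichment_scan", "data.frame")
  out
}

#' Partition the Maps vs. betweenness landscape into quadrants
#'
#' @param compendium a `compendium`.
#' @param maps_threshold,bt_threshold quadrant thresholds; a gene is "hi"
#'   when its value is greater than or equal to the threshold.
#' @return Named character vector of region labels per gene.
#' @export
partition_landscape <- function(compendium, maps_threshold, bt_threshold) {
  genes <- compendium$genes
  bt <- genes$betweenness
  if (all(is.na(bt))) bt <- compute_betweenness(compendium)
  maps_hi <- genes$pathway_maps >= maps_threshold
  bt_hi <- bt >= bt_threshold
  lab <- ifelse(maps_hi & bt_hi, "maps_hi_bt_hi",
                ifelse(!maps_hi & bt_hi, "maps_lo_bt_hi",
                       ifelse(maps_hi, "maps_hi_bt_lo", "maps_lo_bt_lo")))
  setNames(lab, genes$gene_id)
}
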