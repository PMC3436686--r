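#' The compendium data model
#'
#' A `compendium` is the central container of the package: the merged,
#' provenance-annotated ensemble of one or more pathway databases and one or
#' more interaction databases. It is a plain list of data frames:
#'
#' * `genes`: one row per gene of the master list with `gene_id`, `alt_id`,
#'   `function_category`, and the derived metrics `pathway_maps` (number of
#'   database-scoped pathways containing the gene), `degree` (number of
#'   canonical edges incident to it) and `betweenness` (`NA` until computed).
#' * `pathways`: one row per (pathway label, source database) record, with
#'   the member gene set as a list column. Pathways are never merged across
#'   databases by label similarity; the same biological process appearing in
#'   two databases counts as two pathway records.
#' * `edges`: one row per canonical unordered gene pair with the edge weight
#'   `K_E`, the number of distinct source databases reporting the pair.
#' * `annotations`: one row per (pair, source) report with `direction`
#'   (forward/reverse/undirected, relative to canonical order), `sign`
#'   (positive/negative/unsigned), `mechanism` (direct/indirect/unknown),
#'   the raw relation string, and an optional per-source `dataset` tag.
#'
#' @name compendium
#' @seealso [build_ensemble()], [generate_compendium()]
NULL

DIRECTIONS <- c("forward", "reverse", "undirected")
SIGNS <- c("positive", "negative", "unsigned")
MECHANISMS <- c("direct", "indirect", "unknown")

new_compendium <- function(genes, pathways, edges, annotations,
                           interaction_sources, pathway_sources,
                           load_report = list()) {
  structure(
    list(
      genes = genes,
      pathways = pathways,
      edges = edges,
      annotations = annotations,
      interaction_sources = interaction_sources,
      pathway_sources = pathway_sources,
      load_report = load_report
    ),
    class = "compendium"
  )
}

#' Construct a pathway table
#'
#' @param pathway_label character vector of pathway labels.
#' @param source_db character vector of source database names.
#' @param genes list of character vectors, the member gene sets.
#' @return A `pathway_table` data frame with one row per (label, source)
#'   record and a list column `genes`.
#' @export
pathway_table <- function(pathway_label, source_db, genes) {
  if (length(source_db) == 1L) {
    source_db <- rep(source_db, length(pathway_label))
  }
  stopifnot(length(pathway_label) == length(source_db),
            length(pathway_label) == length(genes))
  genes <- unname(lapply(genes, function(g) sort(unique(as.character(g)))))
  key <- paste(pathway_label, source_db, sep = "\r")
  if (anyDuplicated(key)) {
    stop_format("duplicated (pathway_label, source_db) records: %s",
                paste(unique(pathway_label[duplicated(key)]), collapse = ", "))
  }
  out <- data.frame(
    pathway_label = as.character(pathway_label),
    source_db = as.character(source_db),
    n_genes = vapply(genes, length, integer(1)),
    stringsAsFactors = FALSE
  )
  out$genes <- genes
  class(out) <- c("pathway_table", "data.frame")
  out
}

#' Validate compendium invariants
#'
#' Checks referential integrity between the gene, pathway, edge and
#' annotation tables, canonical pair ordering, edge-weight consistency with
#' per-source annotations, and the derived per-gene counts.
#'
#' @param x a `compendium`.
#' @return `x`, invisibly. Errors on the first violated invariant.
#' @export
validate_compendium <- function(x) {
  stopifnot(inherits(x, "compendium"))
  g <- x$genes$gene_id
  assert_that(!anyDuplicated(g), "gene_id not unique in gene table")
  assert_that(all(x$edges$gene_a <= x$edges$gene_b),
              "edges not in canonical pair order")
  assert_that(!anyDuplicated(pair_key(x$edges$gene_a, x$edges$gene_b)),
              "duplicate canonical pairs in edge table")
  assert_that(all(x$edges$gene_a %in% g) && all(x$edges$gene_b %in% g),
              "edge endpoints missing from gene table")
  assert_that(all(unlist(x$pathways$genes) %in% g),
              "pathway member genes missing from gene table")
  assert_that(all(x$annotations$source_db %in% x$interaction_sources),
              "annotation source_db not registered")
  assert_that(all(x$annotations$direction %in% DIRECTIONS) &&
                all(x$annotations$sign %in% SIGNS) &&
                all(x$annotations$mechanism %in% MECHANISMS),
              "annotation vocabulary violation")
  ek <- pair_key(x$edges$gene_a, x$edges$gene_b)
  ak <- pair_key(x$annotations$gene_a, x$annotations$gene_b)
  assert_that(all(ak %in% ek), "annotation for unknown edge")
  kw <- vapply(split(x$annotations$source_db, factor(ak, levels = ek)),
               function(s) length(unique(s)), integer(1))
  assert_that(all(kw >= 1L), "edge without any source annotation")
  assert_that(identical(unname(kw), as.integer(x$edges$edge_weight)),
              "edge_weight inconsistent with annotations")
  maps <- compute_pathway_maps(x)
  assert_that(identical(as.integer(x$genes$pathway_maps),
                        as.integer(unname(maps[g]))),
              "pathway_maps inconsistent with pathway table")
  deg <- tabulate(match(c(x$edges$gene_a, x$edges$gene_b), g), length(g))
  assert_that(identical(as.integer(x$genes$degree), deg),
              "degree inconsistent with edge table")
  invisible(x)
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf(
    "<compendium> %d genes, %d pathway records (%d pathway dbs), %d edges (%d interaction dbs)\n",
    nrow(x$genes), nrow(x$pathways), length(x$pathway_sources),
    nrow(x$edges), length(x$interaction_sources)
  ))
  invisible(x)
}

#' @export
summary.compendium <- function(object, ...) {
  d <- compute_degrees(object)
  wt <- table(object$edges$edge_weight)
  out <- list(
    n_genes = nrow(object$genes),
    n_pathways = nrow(object$pathways),
    n_edges = nrow(object$edges),
    interaction_sources = object$interaction_sources,
    pathway_sources = object$pathway_sources,
    mean_degree_paper = d$summary$mean_degree_paper,
    mean_degree_graph = d$summary$mean_degree_graph,
    edge_weight_table = wt
  )
  class(out) <- "summary.compendium"
  out
}

#' @export
print.summary.compendium <- function(x, ...) {
  cat(sprintf("genes: %d  pathway records: %d  canonical edges: %d\n",
              x$n_genes, x$n_pathways, x$n_edges))
  cat(sprintf("mean degree: %.1f (edges/nodes convention), %.1f (graph convention)\n",
              x$mean_degree_paper, x$mean_degree_graph))
  cat("edge weight distribution:\n")
  print(x$edge_weight_table)
  invisible(x)
}

#' Canonical edges contributed by one interaction source
#'
#' @param compendium a `compendium`.
#' @param source_db registered interaction source name, or `"Ensemble"` for
#'   the full edge table.
#' @return Data frame of canonical pairs (`gene_a`, `gene_b`).
#' @export
edges_for_source <- function(compendium, source_db) {
  if (identical(source_db, "Ensemble")) {
    return(compendium$edges[, c("gene_a", "gene_b")])
  }
  assert_that(source_db %in% compendium$interaction_sources,
              "unknown interaction source '%s'", source_db)
  a <- compendium$annotations
  a <- a[a$source_db == source_db, c("gene_a", "gene_b")]
  unique(a)
}

# Logical pathway-by-gene incidence matrix for a pathway table, over the
# gene universe `gene_ids`.
membership_matrix <- function(pathways, gene_ids) {
  m <- matrix(FALSE, nrow(pathways), length(gene_ids),
              dimnames = list(NULL, gene_ids))
  for (i in seq_len(nrow(pathways))) {
    m[i, match(pathways$genes[[i]], gene_ids)] <- TRUE
  }
  m
}
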