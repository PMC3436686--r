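#' Edge weight distribution
#'
#' Histogram of K_E, the number of source databases reporting each canonical
#' edge. With `restrict_to_source`, the histogram is computed over that
#' source's edges using its per-dataset sub-annotations (the meta-database
#' case: the number of constituent datasets a PPI is found in).
#'
#' @param compendium a `compendium`.
#' @param restrict_to_source optional interaction source name; its
#'   annotations must carry a `dataset` tag.
#' @return Data frame with columns `k`, `count`, `fraction`; counts sum to
#'   the number of (possibly source-restricted) canonical edges and
#'   fractions to 1.
#' @export
edge_weight_distribution <- function(compendium, restrict_to_source = NULL) {
  if (is.null(restrict_to_source)) {
    k <- compendium$edges$edge_weight
  } else {
    assert_that(restrict_to_source %in% compendium$interaction_sources,
                "unknown interaction source '%s'", restrict_to_source)
    a <- compendium$annotations
    a <- a[a$source_db == restrict_to_source, , drop = FALSE]
    assert_that(nrow(a) > 0L, "source '%s' has no edges", restrict_to_source)
    assert_that(!all(is.na(a$dataset)),
                "source '%s' carries no per-dataset sub-annotations",
                restrict_to_source)
    key <- pair_key(a$gene_a, a$gene_b)
    k <- vapply(split(a$dataset, key), function(d) {
      length(unique(d[!is.na(d)]))
    }, integer(1))
    k <- pmax(k, 1L)
  }
  tab <- table(k)
  out <- data.frame(k = as.integer(names(tab)),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / length(k))
  stopifnot(sum(out$count) == length(k))
  out
}

db_edge_keys <- function(compendium, db) {
  e <- edges_for_source(compendium, db)
  pair_key(e$gene_a, e$gene_b)
}

db_gene_set <- function(compendium, db) {
  e <- edges_for_source(compendium, db)
  unique(c(e$gene_a, e$gene_b))
}

#' Directional edge consistency between two interaction sources
#'
#' `C_E(i, j) = e(i, j) / E(i)`, where `E(i)` is the number of database
#' `i` edges whose both endpoints lie in database `j`'s gene set (the genes
#' touched by `j`'s edges) and `e(i, j)` is how many of those are also edges
#' of `j`. Comparison is at the canonical pair level, ignoring direction and
#' sign. The measure is directional: `C_E(i, j) != C_E(j, i)` in general.
#'
#' @param compendium a `compendium`.
#' @param db_i,db_j registered interaction source names.
#' @return A number in \[0, 1\], or `NA` (flagged undefined, never 0) when
#'   database `i` has no edge within `j`'s gene set.
#' @export
edge_consistency <- function(compendium, db_i, db_j) {
  ei <- edges_for_source(compendium, db_i)
  genes_j <- db_gene_set(compendium, db_j)
  qual <- ei$gene_a %in% genes_j & ei$gene_b %in% genes_j
  if (!any(qual)) return(NA_real_)
  keys_i <- pair_key(ei$gene_a, ei$gene_b)[qual]
  keys_j <- db_edge_keys(compendium, db_j)
  sum(keys_i %in% keys_j) / length(keys_i)
}

#' Cross-database edge consistency matrix
#'
#' All ordered pairs of interaction sources; diagonal exactly 1; not
#' symmetric in general. A hierarchical ordering (average linkage on
#' Euclidean row-profile distance, same deterministic tie rule as
#' [cluster_order()]) is attached for heatmap display.
#'
#' @param compendium a `compendium` with at least 2 interaction sources.
#' @return A `consistency_matrix`: list with `db_names`, `values` (rows are
#'   database i, columns database j) and `leaf_order`.
#' @export
consistency_matrix <- function(compendium) {
  dbs <- compendium$interaction_sources
  assert_that(length(dbs) >= 2L, "at least 2 interaction sources are required")
  vals <- matrix(NA_real_, length(dbs), length(dbs),
                 dimnames = list(dbs, dbs))
  for (i in seq_along(dbs)) {
    for (j in seq_along(dbs)) {
      vals[i, j] <- if (i == j) 1 else
        edge_consistency(compendium, dbs[i], dbs[j])
    }
  }
  out <- list(db_names = dbs, values = vals, leaf_order = NULL)
  class(out) <- "consistency_matrix"
  out$leaf_order <- cluster_order(out)
  out
}
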