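#' Jaccard index of two gene sets
#'
#' Intersection size over union size; the pairwise pathway similarity used
#' throughout the package.
#'
#' @param genes_i,genes_j non-empty character vectors (treated as sets).
#' @return A number in \[0, 1\].
#' @export
jaccard_index <- function(genes_i, genes_j) {
  genes_i <- unique(genes_i); genes_j <- unique(genes_j)
  assert_that(length(genes_i) > 0 && length(genes_j) > 0,
              "Jaccard index is undefined for empty sets")
  length(intersect(genes_i, genes_j)) / length(union(genes_i, genes_j))
}

#' All-pairs pathway similarity matrix
#'
#' Computes the Jaccard index between every pair of pathway records
#' (database-scoped; records are never merged by label) and attaches a
#' hierarchical-clustering leaf order for heatmap display.
#'
#' @param pathways a [pathway_table()] with at least 2 records, or a
#'   `compendium`.
#' @return A `similarity_matrix`: list with `pathway_keys` (data frame of
#'   label and source), `values` (symmetric matrix, unit diagonal) and
#'   `leaf_order` (permutation from average-linkage clustering on `1 - J`).
#' @export
similarity_matrix <- function(pathways) {
  if (inherits(pathways, "compendium")) pathways <- pathways$pathways
  n <- nrow(pathways)
  assert_that(n >= 2L, "at least 2 pathway records are required")
  universe <- sort(unique(unlist(pathways$genes)))
  m <- membership_matrix(pathways, universe) * 1L
  inter <- tcrossprod(m)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  vals <- inter / uni
  keys <- paste(pathways$pathway_label, pathways$source_db, sep = "|")
  dimnames(vals) <- list(keys, keys)
  out <- list(
    pathway_keys = data.frame(pathway_label = pathways$pathway_label,
                              source_db = pathways$source_db,
                              stringsAsFactors = FALSE),
    values = vals,
    leaf_order = NULL
  )
  class(out) <- "similarity_matrix"
  out$leaf_order <- cluster_order(out)
  out
}

#' Deterministic average-linkage leaf order
#'
#' Agglomerative clustering with average (UPGMA) linkage on a distance
#' matrix, merging the lexicographically smallest index pair on ties and
#' placing the longer-established cluster on the left, so the leaf order is
#' fully deterministic (an all-tied matrix preserves input order).
#'
#' @param x a `similarity_matrix` (clustered on `1 - J`), a
#'   `consistency_matrix` (clustered on Euclidean row-profile distance), or
#'   a square distance matrix.
#' @return Integer permutation of the row indices.
#' @export
cluster_order <- function(x) {
  d <- if (inherits(x, "similarity_matrix")) {
    1 - x$values
  } else if (inherits(x, "consistency_matrix")) {
    v <- x$values
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    as.matrix(dist(v))
  } else {
    as.matrix(x)
  }
  n <- nrow(d)
  if (n == 1L) return(1L)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  dm <- d
  diag(dm) <- Inf
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best_i <- best_j <- 0L
    best_d <- Inf
    for (a in seq_along(idx)) {
      i <- idx[a]
      for (b in seq_along(idx)) {
        j <- idx[b]
        if (j <= i) next
        if (dm[i, j] < best_d) {          # strict <: first minimum wins ties
          best_d <- dm[i, j]; best_i <- i; best_j <- j
        }
      }
    }
    i <- best_i; j <- best_j
    # average-linkage update into slot i (the earlier cluster, kept left)
    upd <- idx[idx != i & idx != j]
    dm[i, upd] <- (sizes[i] * dm[i, upd] + sizes[j] * dm[j, upd]) /
      (sizes[i] + sizes[j])
    dm[upd, i] <- dm[i, upd]
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  members[[which(active)]]
}
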