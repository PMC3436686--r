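#' Directed view of a compendium
#'
#' Projects the annotated pair-level edge table onto a directed graph: one
#' arc per ordered gene pair supported by at least one (filtered) source
#' annotation. A forward annotation yields `gene_a -> gene_b`, a reverse one
#' the opposite arc, and an undirected one both arcs unless
#' `directed_only = TRUE` (the default, matching the restriction of the path
#' analyses to directed mechanistic edges). Parallel arcs from different
#' sources collapse.
#'
#' @param compendium a `compendium`.
#' @param directed_only drop undirected annotations (default `TRUE`).
#' @param sources optional subset of interaction sources.
#' @param mechanisms optional subset of mechanism annotations.
#' @param signs optional subset of sign annotations.
#' @param min_weight optional minimum edge weight K_E.
#' @return A `directed_view`: list with `arcs` (data frame `from`, `to`),
#'   `genes` (vertex universe) and the filter used.
#' @export
directed_view <- function(compendium, directed_only = TRUE, sources = NULL,
                          mechanisms = NULL, signs = NULL,
                          min_weight = NULL) {
  a <- compendium$annotations
  if (!is.null(sources)) a <- a[a$source_db %in% sources, , drop = FALSE]
  if (!is.null(mechanisms)) a <- a[a$mechanism %in% mechanisms, , drop = FALSE]
  if (!is.null(signs)) a <- a[a$sign %in% signs, , drop = FALSE]
  if (!is.null(min_weight)) {
    ek <- pair_key(compendium$edges$gene_a, compendium$edges$gene_b)
    w <- compendium$edges$edge_weight[match(pair_key(a$gene_a, a$gene_b), ek)]
    a <- a[w >= min_weight, , drop = FALSE]
  }
  if (directed_only) a <- a[a$direction != "undirected", , drop = FALSE]
  fwd <- a[a$direction == "forward", c("gene_a", "gene_b")]
  rev <- a[a$direction == "reverse", c("gene_b", "gene_a")]
  und <- a[a$direction == "undirected", , drop = FALSE]
  arcs <- rbind(setNames(fwd, c("from", "to")),
                setNames(rev, c("from", "to")),
                if (nrow(und)) setNames(und[, c("gene_a", "gene_b")],
                                        c("from", "to")),
                if (nrow(und)) setNames(und[, c("gene_b", "gene_a")],
                                        c("from", "to")))
  arcs <- unique(arcs)
  rownames(arcs) <- NULL
  if (nrow(arcs) == 0L) {
    warning("directed view is empty under the given filter", call. = FALSE)
  }
  structure(list(arcs = arcs, genes = compendium$genes$gene_id,
                 filter = list(directed_only = directed_only,
                               sources = sources, mechanisms = mechanisms,
                               signs = signs, min_weight = min_weight)),
            class = "directed_view")
}

view_adjacency <- function(view) {
  genes <- view$genes
  from <- match(view$arcs$from, genes)
  to <- match(view$arcs$to, genes)
  adj <- split(to, factor(from, levels = seq_along(genes)))
  lapply(adj, function(v) sort(unname(v)))
}

view_igraph <- function(view) {
  igraph::graph_from_data_frame(view$arcs, directed = TRUE,
                                vertices = view$genes)
}

#' All shortest directed paths between two genes
#'
#' Unit edge weights; every distinct shortest simple path is returned,
#' lexicographically sorted by node sequence.
#'
#' @param view a [directed_view()].
#' @param source,target gene ids present in the view.
#' @return List with `length` (`NA` if unreachable) and `paths` (list of
#'   character node sequences, empty if unreachable).
#' @export
shortest_paths_all <- function(view, source, target) {
  assert_that(all(c(source, target) %in% view$genes),
              "source/target not in the graph")
  g <- view_igraph(view)
  d <- igraph::distances(g, v = source, to = target, mode = "out")[1, 1]
  if (!is.finite(d)) return(list(length = NA_integer_, paths = list()))
  sp <- igraph::all_shortest_paths(g, from = source, to = target,
                                   mode = "out")$vpaths
  paths <- lapply(sp, function(p) igraph::V(g)$name[as.integer(p)])
  paths <- paths[order(vapply(paths, paste, character(1), collapse = "\r"))]
  list(length = as.integer(d), paths = paths)
}

# Core bounded simple-path counter: iterative (explicit stack) depth-first
# search with an on-path marker; counts paths by exact edge length.
count_simple_paths <- function(adj, s, t, max_length, max_paths = 1e7) {
  counts <- numeric(max_length)
  if (s == t) return(list(counts = counts, truncated = FALSE))
  n <- length(adj)
  onpath <- logical(n)
  node <- integer(max_length + 1L)
  ptr <- integer(max_length + 1L)
  depth <- 1L
  node[1L] <- s; ptr[1L] <- 0L; onpath[s] <- TRUE
  total <- 0
  truncated <- FALSE
  repeat {
    ptr[depth] <- ptr[depth] + 1L
    nbrs <- adj[[node[depth]]]
    if (ptr[depth] > length(nbrs)) {
      onpath[node[depth]] <- FALSE
      depth <- depth - 1L
      if (depth == 0L) break
      next
    }
    v <- nbrs[ptr[depth]]
    if (v == t) {
      counts[depth] <- counts[depth] + 1
      total <- total + 1
      if (total >= max_paths) { truncated <- TRUE; break }
      next
    }
    if (onpath[v] || depth == max_length) next
    depth <- depth + 1L
    node[depth] <- v
    ptr[depth] <- 0L
    onpath[v] <- TRUE
  }
  list(counts = counts, truncated = truncated)
}

#' Bounded simple-path enumeration
#'
#' Counts all simple directed paths (no repeated node) from `source` to
#' `target` of each exact edge length `1..max_length`, by iterative
#' depth-first search. Path counts grow exponentially with length; the
#' search stops (and flags the result truncated) at `max_paths`.
#'
#' @param view a [directed_view()].
#' @param source,target gene ids.
#' @param max_length maximum path length in edges (default and cap 8).
#' @param required_node optional gene: also report the fraction of
#'   enumerated paths passing through it, see [through_fraction()].
#' @param max_paths count ceiling (default 1e7).
#' @return A `path_enumeration`: list with `counts_by_length`,
#'   `cumulative_counts`, `shortest_length`, `shortest_paths`,
#'   `through_fraction` (or `NA`), and `truncated`.
#' @export
enumerate_paths <- function(view, source, target, max_length = 8L,
                            required_node = NULL, max_paths = 1e7) {
  assert_that(max_length >= 1L, "max_length must be >= 1")
  assert_that(!identical(source, target), "source and target must differ")
  assert_that(all(c(source, target) %in% view$genes),
              "source/target not in the graph")
  adj <- view_adjacency(view)
  s <- match(source, view$genes)
  t <- match(target, view$genes)
  res <- count_simple_paths(adj, s, t, max_length, max_paths)
  counts <- setNames(res$counts, seq_len(max_length))
  sp <- shortest_paths_all(view, source, target)
  tf <- if (!is.null(required_node)) {
    through_fraction(view, source, target, max_length,
                     required_node = required_node, max_paths = max_paths)
  } else NA_real_
  structure(list(
    counts_by_length = counts,
    cumulative_counts = setNames(cumsum(counts), names(counts)),
    shortest_length = sp$length,
    shortest_paths = sp$paths,
    through_fraction = tf,
    truncated = res$truncated
  ), class = "path_enumeration")
}

#' Fraction of bounded paths passing through a required node
#'
#' Among all simple paths of length at most `max_length` from `source` to
#' `target`, the fraction containing `required_node` at any position
#' (`position = "any"`, the default) or as the first hop out of the source
#' (`position = "first_hop"`). The complement is the bypass fraction: routes
#' that skip a mechanistically required intermediate such as the receptor
#' for an extracellular ligand.
#'
#' @inheritParams enumerate_paths
#' @param required_node the gene that plausible routes must traverse.
#' @param position `"any"` or `"first_hop"`.
#' @return A fraction in \[0, 1\], or `NA` (flagged, with a warning) when no
#'   path exists.
#' @export
through_fraction <- function(view, source, target, max_length = 8L,
                             required_node, position = c("any", "first_hop"),
                             max_paths = 1e7) {
  position <- match.arg(position)
  assert_that(required_node %in% view$genes,
              "required_node not in the graph")
  adj <- view_adjacency(view)
  s <- match(source, view$genes)
  t <- match(target, view$genes)
  q <- match(required_node, view$genes)
  total <- sum(count_simple_paths(adj, s, t, max_length, max_paths)$counts)
  if (total == 0) {
    warning("no path from source to target; through fraction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (position == "first_hop") {
    adj_first <- adj
    adj_first[[s]] <- intersect(adj[[s]], q)
    through <- sum(count_simple_paths(adj_first, s, t, max_length,
                                      max_paths)$counts)
    return(through / total)
  }
  if (q == s || q == t) return(1)
  adj_del <- lapply(adj, function(v) v[v != q])
  adj_del[[q]] <- integer(0)
  avoiding <- sum(count_simple_paths(adj_del, s, t, max_length,
                                     max_paths)$counts)
  (total - avoiding) / total
}

#' Expand a linear scaffold by one-step intermediates
#'
#' Finds every non-scaffold gene X with a directed in-arc from a scaffold
#' node `S_i` and a directed out-arc to a scaffold node `S_j`, for any
#' ordered scaffold pair. Each (X, i, j) link is classified: `parallel` when
#' `j = i + 1` (an alternative route alongside one scaffold step),
#' `feed-forward` when `i < j - 1` (skipping ahead), `feed-back` when
#' `i >= j`.
#'
#' @param view a [directed_view()].
#' @param chain ordered character vector of scaffold genes (all present in
#'   the view).
#' @return A `scaffold_expansion` data frame (`gene`, `from`, `to`,
#'   `from_index`, `to_index`, `class`), with attribute `"n_distinct"` (each
#'   intermediate gene counted once).
#' @export
expand_scaffold <- function(view, chain) {
  chain <- as.character(chain)
  assert_that(all(chain %in% view$genes), "scaffold genes missing from graph")
  arcs <- view$arcs
  from_sc <- arcs[arcs$from %in% chain & !(arcs$to %in% chain), , drop = FALSE]
  to_sc <- arcs[arcs$to %in% chain & !(arcs$from %in% chain), , drop = FALSE]
  cand <- intersect(from_sc$to, to_sc$from)
  rows <- lapply(cand, function(x) {
    i <- match(from_sc$from[from_sc$to == x], chain)
    j <- match(to_sc$to[to_sc$from == x], chain)
    g <- expand.grid(i = i, j = j)
    data.frame(gene = x, from = chain[g$i], to = chain[g$j],
               from_index = g$i, to_index = g$j,
               class = scaffold_class(g$i, g$j), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), from = character(), to = character(),
               from_index = integer(), to_index = integer(),
               class = character(), stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$from_index, out$to_index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_distinct") <- length(unique(out$gene))
  class(out) <- c("scaffold_expansion", "data.frame")
  out
}

#' High-weight enrichment of scaffold edges
#'
#' Tests whether the consecutive edges of a scaffold are enriched for
#' high-weight edges (K_E at or above a threshold) relative to the whole
#' compendium, by the upper-tail hypergeometric probability of observing at
#' least as many high-weight edges in a sample of the scaffold's size.
#'
#' @param compendium a `compendium`.
#' @param chain ordered scaffold genes; every consecutive pair must exist as
#'   a canonical edge (a validation error lists missing pairs).
#' @param high_weight_threshold minimum K_E counted as high weight.
#' @return List with `p_value`, `edge_weights` (named per scaffold edge),
#'   `n_high_sample`, `n_high_population`, `n_population`.
#' @export
scaffold_edge_enrichment <- function(compendium, chain,
                                     high_weight_threshold) {
  chain <- as.character(chain)
  cp <- canonicalize_pairs(chain[-length(chain)], chain[-1])
  keys <- pair_key(cp$gene_a, cp$gene_b)
  ek <- pair_key(compendium$edges$gene_a, compendium$edges$gene_b)
  i <- match(keys, ek)
  if (anyNA(i)) {
    miss <- paste(chain[-length(chain)][is.na(i)], chain[-1][is.na(i)],
                  sep = "->")
    stop_format("scaffold edges missing from compendium: %s",
                paste(miss, collapse = ", "))
  }
  w <- compendium$edges$edge_weight[i]
  names(w) <- paste(chain[-length(chain)], chain[-1], sep = "->")
  pop <- compendium$edges$edge_weight
  n_pop <- length(pop)
  n_succ <- sum(pop >= high_weight_threshold)
  k <- length(w)
  obs <- sum(w >= high_weight_threshold)
  p <- phyper(obs - 1, n_succ, n_pop - n_succ, k, lower.tail = FALSE)
  list(p_value = p, edge_weights = w, n_high_sample = obs,
       n_high_population = n_succ, n_population = n_pop)
}
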