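#' Default relation-string vocabulary
#'
#' Maps common Cytoscape/Pathway Commons SIF relation strings to a
#' (direction, sign, mechanism) triple. Unknown relation strings never fail a
#' load: they map to (undirected, unsigned, unknown) with the raw string
#' preserved in the record.
#'
#' @return A data frame with columns `relation`, `direction`, `sign`,
#'   `mechanism`.
#' @export
default_relation_map <- function() {
  read_relation_map(system.file("extdata", "relation_map.tsv",
                                package = "pkncompendium", mustWork = TRUE))
}

#' Read a relation map file
#'
#' @param path TSV with header columns relation, direction, sign, mechanism.
#' @return A relation map data frame, validated against the controlled
#'   vocabularies.
#' @export
read_relation_map <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("relation", "direction", "sign", "mechanism")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop_format("relation map missing column '%s'", miss[1])
  assert_that(all(m$direction %in% DIRECTIONS) && all(m$sign %in% SIGNS) &&
                all(m$mechanism %in% MECHANISMS),
              "relation map uses terms outside the controlled vocabulary")
  m
}

#' Read pathway gene sets
#'
#' Two dialects are supported: long-form TSV with one row per
#' (pathway, source, gene) membership, and GMT-like files with one row per
#' pathway (`name<TAB>description<TAB>gene1<TAB>gene2...`).
#'
#' @param path input file.
#' @param dialect `"long"` or `"gmt"`.
#' @param source_db for GMT input, the database name to assign to every
#'   record (default: the GMT description field, per record).
#' @return A [pathway_table()] with genes deduplicated within each record.
#'   Records with an empty gene set are rejected with a warning. Duplicated
#'   membership rows are idempotent.
#' @export
read_pathway_table <- function(path, dialect = c("long", "gmt"),
                               source_db = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "pathway file '%s' does not exist", path)
  if (dialect == "long") {
    d <- read.delim(path, stringsAsFactors = FALSE)
    names(d) <- sub("^pathway_label$", "pathway", names(d))
    names(d) <- sub("^source_db$", "source", names(d))
    names(d) <- sub("^gene_id$", "gene", names(d))
    for (col in c("pathway", "source", "gene")) {
      if (!col %in% names(d)) {
        stop_format("pathway table '%s' is missing column '%s'", path, col)
      }
    }
    d$gene <- trimws(as.character(d$gene))
    recs <- split(d$gene, paste(d$pathway, d$source, sep = "\r"))
    keys <- do.call(rbind, strsplit(names(recs), "\r", fixed = TRUE))
    labels <- keys[, 1]; dbs <- keys[, 2]
    genes <- lapply(recs, function(g) unique(g[nzchar(g)]))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, integer(1)) < 2L
    if (any(bad)) stop_format("GMT file '%s': line %d has fewer than 2 fields",
                              path, which(bad)[1])
    labels <- vapply(fields, `[[`, character(1), 1L)
    dbs <- if (is.null(source_db)) {
      vapply(fields, `[[`, character(1), 2L)
    } else rep(source_db, length(fields))
    genes <- lapply(fields, function(f) {
      g <- trimws(f[-(1:2)])
      unique(g[nzchar(g)])
    })
  }
  empty <- vapply(genes, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sprintf("rejected %d pathway record(s) with empty gene set: %s",
                    sum(empty), paste(labels[empty], collapse = ", ")),
            call. = FALSE)
  }
  # restore original encounter order (split() sorts keys)
  first_seen <- order(match(paste(labels, dbs, sep = "\r"),
                            unique(paste(labels, dbs, sep = "\r"))))
  keep <- first_seen[!empty[first_seen]]
  pathway_table(labels[keep], dbs[keep], genes[keep])
}

empty_interactions <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             direction = character(), sign = character(),
             mechanism = character(), raw_relation = character(),
             dataset = character(), source_db = character(),
             stringsAsFactors = FALSE)
}

map_relations <- function(rel, relation_map) {
  i <- match(rel, relation_map$relation)
  data.frame(
    direction = ifelse(is.na(i), "undirected", relation_map$direction[i]),
    sign = ifelse(is.na(i), "unsigned", relation_map$sign[i]),
    mechanism = ifelse(is.na(i), "unknown", relation_map$mechanism[i]),
    raw_relation = rel,
    stringsAsFactors = FALSE
  )
}

#' Read raw interaction records from one source database
#'
#' Supports Cytoscape SIF (`nodeA<TAB>relation<TAB>nodeB [nodeC ...]`; a line
#' with several targets yields one record per target) and annotated TSV with
#' header columns `gene_a`, `gene_b` and any of `direction`, `sign`,
#' `mechanism`, `relation`, `dataset`. Relation strings are mapped through
#' `relation_map`; unknown strings map to (undirected, unsigned, unknown)
#' with the raw string preserved. Self-loop rows are dropped and counted in
#' the load report attached as attribute `"load_report"`; rows with a blank
#' endpoint are a format error.
#'
#' @param path input file.
#' @param source_db database name recorded on every returned record.
#' @param dialect `"sif"` or `"tsv"`.
#' @param relation_map a relation map data frame, see
#'   [default_relation_map()].
#' @return Data frame of raw (uncanonicalized) interaction records;
#'   `direction` is relative to the as-read endpoint order.
#' @export
read_interactions <- function(path, source_db, dialect = c("sif", "tsv"),
                              relation_map = default_relation_map()) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "interaction file '%s' does not exist", path)
  if (dialect == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    sep <- if (any(grepl("\t", lines, fixed = TRUE))) "\t" else " +"
    fields <- strsplit(lines, sep)
    n <- vapply(fields, length, integer(1))
    if (any(n == 2L)) {
      stop_format("SIF '%s': line %d has a relation but no target node",
                  path, which(n == 2L)[1])
    }
    fields <- fields[n >= 3L]  # single-field lines are isolated nodes
    a <- rep(vapply(fields, `[[`, character(1), 1L),
             vapply(fields, length, integer(1)) - 2L)
    rel <- rep(vapply(fields, `[[`, character(1), 2L),
               vapply(fields, length, integer(1)) - 2L)
    b <- unlist(lapply(fields, function(f) f[-(1:2)]))
    if (any(!nzchar(trimws(a))) || any(!nzchar(trimws(b)))) {
      stop_format("SIF '%s': blank endpoint", path)
    }
    rec <- cbind(data.frame(gene_a = trimws(a), gene_b = trimws(b),
                            stringsAsFactors = FALSE),
                 map_relations(rel, relation_map))
    rec$dataset <- NA_character_
  } else {
    d <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
    for (col in c("gene_a", "gene_b")) {
      if (!col %in% names(d)) {
        stop_format("interaction table '%s' is missing column '%s'", path, col)
      }
    }
    if (nrow(d) && (any(!nzchar(trimws(d$gene_a))) ||
                    any(!nzchar(trimws(d$gene_b))))) {
      stop_format("interaction table '%s': blank endpoint", path)
    }
    base <- if ("relation" %in% names(d)) {
      map_relations(d$relation, relation_map)
    } else {
      data.frame(direction = rep("undirected", nrow(d)),
                 sign = rep("unsigned", nrow(d)),
                 mechanism = rep("unknown", nrow(d)),
                 raw_relation = rep(NA_character_, nrow(d)),
                 stringsAsFactors = FALSE)
    }
    for (col in c("direction", "sign", "mechanism")) {
      if (col %in% names(d)) base[[col]] <- d[[col]]
    }
    assert_that(all(base$direction %in% DIRECTIONS) &&
                  all(base$sign %in% SIGNS) &&
                  all(base$mechanism %in% MECHANISMS),
                "interaction table '%s' uses terms outside the controlled vocabulary",
                path)
    rec <- cbind(data.frame(gene_a = trimws(d$gene_a),
                            gene_b = trimws(d$gene_b),
                            stringsAsFactors = FALSE), base)
    rec$dataset <- if ("dataset" %in% names(d)) d$dataset else NA_character_
  }
  n_raw <- nrow(rec)
  self <- rec$gene_a == rec$gene_b
  rec <- rec[!self, , drop = FALSE]
  rec$source_db <- source_db
  rownames(rec) <- NULL
  attr(rec, "load_report") <- list(n_raw = n_raw,
                                   n_self_loops_dropped = sum(self),
                                   n_records = nrow(rec))
  rec
}

#' Expand a molecular complex into pairwise interaction records
#'
#' Complexes reported as n-member groups are expanded combinatorially into
#' all `choose(n, 2)` undirected pairwise records, each inheriting the source
#' database and mechanism.
#'
#' @param members character vector of complex member gene ids (`n >= 2`).
#' @param source_db database the complex was reported by.
#' @param mechanism mechanism annotation inherited by each pair (default
#'   `"direct"`: physical complex co-membership).
#' @return Data frame of raw interaction records; empty (with a warning) if
#'   fewer than 2 distinct members are supplied.
#' @export
expand_complex <- function(members, source_db, mechanism = "direct") {
  members <- unique(as.character(members))
  if (length(members) < 2L) {
    warning("complex with fewer than 2 distinct members; no pairs generated",
            call. = FALSE)
    return(empty_interactions())
  }
  p <- combn(members, 2L)
  data.frame(gene_a = p[1L, ], gene_b = p[2L, ],
             direction = "undirected", sign = "unsigned",
             mechanism = mechanism, raw_relation = "complex",
             dataset = NA_character_, source_db = source_db,
             stringsAsFactors = FALSE)
}

#' Build the ensemble compendium
#'
#' Merges pathway gene sets and per-source raw interaction records into a
#' single validated [compendium]. The master gene list is the union of the
#' pathway gene sets; interactions are kept only when both endpoints are on
#' the master list. Pairs are canonicalized (unordered), per-source
#' annotations are concatenated, and the derived quantities (edge weight,
#' pathway maps, degree) are computed. A load report with per-source raw,
#' dropped and kept counts is stored in the result.
#'
#' @param pathways a [pathway_table()] (or list of them, row-bound).
#' @param interactions a raw interaction record data frame from
#'   [read_interactions()] / [expand_complex()], or a list of them.
#' @param gene_annotations optional data frame with `gene_id` and any of
#'   `alt_id`, `function_category`; genes without an entry get category
#'   `"other"`.
#' @param id_map optional two-column data frame (`from`, `to`) applied
#'   verbatim to every identifier before merging; unmapped ids pass through.
#'   Two distinct inputs mapping onto one id are merged with a warning.
#' @return A validated `compendium`.
#' @export
build_ensemble <- function(pathways, interactions, gene_annotations = NULL,
                           id_map = NULL) {
  if (is.list(pathways) && !inherits(pathways, "data.frame")) {
    pathways <- do.call(rbind, pathways)
  }
  if (inherits(interactions, "data.frame")) interactions <- list(interactions)
  assert_that(nrow(pathways) >= 1L, "at least one pathway record is required")
  raw_reports <- lapply(interactions, attr, "load_report")
  raw_reports <- raw_reports[!vapply(raw_reports, is.null, logical(1))]
  interactions <- do.call(rbind, interactions)
  if (is.null(interactions)) interactions <- empty_interactions()

  remap <- function(x) x
  if (!is.null(id_map)) {
    assert_that(all(c("from", "to") %in% names(id_map)),
                "id_map must have columns 'from' and 'to'")
    coll <- unique(id_map$to[duplicated(id_map$to)])
    coll <- coll[vapply(coll, function(t) {
      length(unique(id_map$from[id_map$to == t])) > 1L
    }, logical(1))]
    if (length(coll)) {
      warning(sprintf("id_map merges multiple inputs onto: %s",
                      paste(coll, collapse = ", ")), call. = FALSE)
    }
    remap <- function(x) {
      i <- match(x, id_map$from)
      out <- ifelse(is.na(i), x, id_map$to[i])
      if (anyNA(i) && any(!is.na(i))) {
        # pass-through is expected; only warn when a mapping table was given
        unmapped <- unique(x[is.na(i)])
        if (length(unmapped)) {
          warning(sprintf("%d identifier(s) not in id_map passed through unchanged",
                          length(unmapped)), call. = FALSE)
        }
      }
      out
    }
  }

  pathways$genes <- lapply(pathways$genes, function(g) sort(unique(remap(g))))
  pathways$n_genes <- vapply(pathways$genes, length, integer(1))
  interactions$gene_a <- remap(interactions$gene_a)
  interactions$gene_b <- remap(interactions$gene_b)

  master <- sort(unique(unlist(pathways$genes)))
  src_order <- unique(interactions$source_db)

  # per-source filter accounting
  self <- interactions$gene_a == interactions$gene_b
  inside <- interactions$gene_a %in% master & interactions$gene_b %in% master
  keep <- !self & inside
  report <- lapply(src_order, function(s) {
    i <- interactions$source_db == s
    list(n_raw = sum(i),
         n_self_loops_dropped = sum(i & self),
         n_outside_master_dropped = sum(i & !self & !inside),
         n_kept = sum(i & keep))
  })
  names(report) <- src_order
  kept <- interactions[keep, , drop = FALSE]

  cp <- canonicalize_pairs(kept$gene_a, kept$gene_b)
  ann <- data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b,
                    source_db = kept$source_db,
                    direction = flip_direction(kept$direction, cp$swapped),
                    sign = kept$sign, mechanism = kept$mechanism,
                    raw_relation = kept$raw_relation, dataset = kept$dataset,
                    stringsAsFactors = FALSE)
  # one annotation row per (pair, source, direction, sign, mechanism, dataset)
  ann <- unique(ann)
  ann <- ann[order(ann$gene_a, ann$gene_b, ann$source_db), , drop = FALSE]
  rownames(ann) <- NULL

  ek <- unique(pair_key(ann$gene_a, ann$gene_b))
  split_ab <- do.call(rbind, strsplit(ek, "\r", fixed = TRUE))
  edges <- if (length(ek)) {
    data.frame(gene_a = split_ab[, 1], gene_b = split_ab[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(), gene_b = character(),
               stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  akey <- pair_key(ann$gene_a, ann$gene_b)
  ekey <- pair_key(edges$gene_a, edges$gene_b)
  edges$edge_weight <- as.integer(vapply(
    split(ann$source_db, factor(akey, levels = ekey)),
    function(s) length(unique(s)), integer(1)))

  genes <- data.frame(gene_id = master, alt_id = NA_character_,
                      function_category = "other", stringsAsFactors = FALSE)
  if (!is.null(gene_annotations)) {
    assert_that("gene_id" %in% names(gene_annotations),
                "gene_annotations must have a gene_id column")
    ga <- gene_annotations
    ga$gene_id <- remap(as.character(ga$gene_id))
    i <- match(genes$gene_id, ga$gene_id)
    if ("alt_id" %in% names(ga)) genes$alt_id <- ga$alt_id[i]
    if ("function_category" %in% names(ga)) {
      fc <- ga$function_category[i]
      genes$function_category <- ifelse(is.na(fc), "other", fc)
    }
  }
  maps <- table(factor(unlist(pathways$genes), levels = master))
  genes$pathway_maps <- as.integer(maps)
  genes$degree <- tabulate(match(c(edges$gene_a, edges$gene_b), master),
                           length(master))
  genes$betweenness <- NA_real_

  comp <- new_compendium(
    genes = genes, pathways = pathways, edges = edges, annotations = ann,
    interaction_sources = src_order,
    pathway_sources = unique(pathways$source_db),
    load_report = list(per_source = report,
                       per_source_raw_files = raw_reports,
                       n_master_genes = length(master),
                       n_canonical_edges = nrow(edges))
  )
  validate_compendium(comp)
}
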