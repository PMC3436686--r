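write_tsv <- function(d, path) {
  # list columns are not written; callers pass flat frames
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
}

pathways_long <- function(pathways) {
  n <- vapply(pathways$genes, length, integer(1))
  data.frame(pathway_label = rep(pathways$pathway_label, n),
             source_db = rep(pathways$source_db, n),
             gene_id = unlist(pathways$genes),
             stringsAsFactors = FALSE)
}

#' Write a compendium to a directory
#'
#' Emits a Cytoscape-compatible SIF edge list (`edges.sif`), a node attribute
#' TSV (`nodes.tsv`), an edge attribute TSV with one row per source
#' annotation (`edge_annotations.tsv`), the canonical edge table
#' (`edges.tsv`), the pathway membership table in long form
#' (`pathways.tsv`), and a JSON provenance summary (`provenance.json`).
#' The written set round-trips: [read_compendium()] on the output directory
#' reproduces every table exactly, and a write/read/write cycle is
#' byte-identical.
#'
#' @param compendium a validated `compendium`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_compendium <- function(compendium, out_dir) {
  validate_compendium(compendium)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "cannot create output directory '%s'",
              out_dir)
  paths <- file.path(out_dir, c("edges.sif", "nodes.tsv", "edges.tsv",
                                "edge_annotations.tsv", "pathways.tsv",
                                "provenance.json"))
  names(paths) <- c("sif", "nodes", "edges", "annotations", "pathways",
                    "provenance")
  sif <- sprintf("%s\tinteracts\t%s",
                 compendium$edges$gene_a, compendium$edges$gene_b)
  writeLines(sif, paths["sif"], useBytes = TRUE)
  write_tsv(compendium$genes, paths["nodes"])
  write_tsv(compendium$edges, paths["edges"])
  write_tsv(compendium$annotations, paths["annotations"])
  write_tsv(pathways_long(compendium$pathways), paths["pathways"])
  prov <- list(
    interaction_sources = compendium$interaction_sources,
    pathway_sources = compendium$pathway_sources,
    n_genes = nrow(compendium$genes),
    n_pathways = nrow(compendium$pathways),
    n_edges = nrow(compendium$edges),
    load_report = compendium$load_report
  )
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Read a compendium written by [write_compendium()]
#'
#' @param dir directory produced by [write_compendium()].
#' @return A validated `compendium` identical (all tables) to the one
#'   written.
#' @export
read_compendium <- function(dir) {
  need <- file.path(dir, c("nodes.tsv", "edges.tsv", "edge_annotations.tsv",
                           "pathways.tsv", "provenance.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop_format("compendium directory '%s' is missing %s", dir,
                paste(basename(missing), collapse = ", "))
  }
  genes <- read.delim(need[1], stringsAsFactors = FALSE,
                      colClasses = c(gene_id = "character",
                                     alt_id = "character",
                                     function_category = "character"))
  edges <- read.delim(need[2], stringsAsFactors = FALSE,
                      colClasses = c(gene_a = "character",
                                     gene_b = "character"))
  ann <- read.delim(need[3], stringsAsFactors = FALSE,
                    colClasses = "character")
  pw <- read.delim(need[4], stringsAsFactors = FALSE,
                   colClasses = "character")
  prov <- jsonlite::read_json(need[5], simplifyVector = TRUE)
  key <- paste(pw$pathway_label, pw$source_db, sep = "\r")
  recs <- split(pw$gene_id, factor(key, levels = unique(key)))
  labels <- do.call(rbind, strsplit(unique(key), "\r", fixed = TRUE))
  pathways <- pathway_table(labels[, 1], labels[, 2], recs)
  genes$pathway_maps <- as.integer(genes$pathway_maps)
  genes$degree <- as.integer(genes$degree)
  genes$betweenness <- as.numeric(genes$betweenness)
  edges$edge_weight <- as.integer(edges$edge_weight)
  comp <- new_compendium(
    genes = genes, pathways = pathways, edges = edges, annotations = ann,
    interaction_sources = as.character(prov$interaction_sources),
    pathway_sources = as.character(prov$pathway_sources),
    load_report = prov$load_report
  )
  validate_compendium(comp)
}
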