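#' Default pipeline configuration
#'
#' A fully serializable (JSON) configuration for [run_pipeline()]. Either
#' `simulate` (a [synthetic_config()] argument list) or `inputs` (paths to a
#' pathway table, per-source interaction files, and optional gene
#' annotation / id-map tables) must describe where the compendium comes
#' from. Every stage can be toggled and parameterized.
#'
#' @param simulate named list of [synthetic_config()] arguments, or `NULL`.
#' @param inputs named list with `pathways` (path + dialect), `interactions`
#'   (list of `source_db`/`path`/`dialect`), optional `gene_annotations`,
#'   `id_map`, `relation_map`; or `NULL`.
#' @param stages named logical list toggling `topology`, `similarity`,
#'   `concordance`, `modularity`, `paths`.
#' @param params stage parameters: `n_randomizations`, `seed`,
#'   `enrichment` (list of region/category), `queries` (list of path
#'   queries: `source`, `target`, `max_length`, `required_node`),
#'   `scaffold_chain`.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(simulate = list(), inputs = NULL,
                            stages = list(topology = TRUE, similarity = TRUE,
                                          concordance = TRUE,
                                          modularity = TRUE, paths = FALSE),
                            params = list(n_randomizations = 100L,
                                          seed = 1L)) {
  structure(list(simulate = simulate, inputs = inputs, stages = stages,
                 params = params),
            class = c("run_config", "list"))
}

read_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  structure(config, class = c("run_config", "list"))
}

load_inputs <- function(inputs) {
  pw <- read_pathway_table(inputs$pathways$path,
                           dialect = inputs$pathways$dialect %||% "long")
  rmap <- if (!is.null(inputs$relation_map)) {
    read_relation_map(inputs$relation_map)
  } else default_relation_map()
  batches <- lapply(inputs$interactions, function(x) {
    read_interactions(x$path, x$source_db, dialect = x$dialect %||% "tsv",
                      relation_map = rmap)
  })
  ga <- if (!is.null(inputs$gene_annotations)) {
    read.delim(inputs$gene_annotations, stringsAsFactors = FALSE,
               colClasses = "character")
  }
  idm <- if (!is.null(inputs$id_map)) {
    read.delim(inputs$id_map, stringsAsFactors = FALSE,
               colClasses = "character")
  }
  build_ensemble(pw, batches, gene_annotations = ga, id_map = idm)
}

#' Write synthetic inputs consumable by the pipeline
#'
#' Runs the synthetic generator and writes its output in the package's input
#' formats: a long-form pathway table, one annotated interaction TSV per
#' source, a gene annotation table, the planted truth as JSON, and an echo
#' of the generator configuration. Regeneration with the same seed is
#' file-identical.
#'
#' @param config a [synthetic_config()] (or argument list for one).
#' @param out_dir output directory.
#' @return Invisibly, the list returned by the generator.
#' @export
simulate_inputs <- function(config, out_dir) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  gen <- if (!is.null(config$scaffold)) {
    generate_scaffold_network(config)
  } else {
    generate_compendium(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- gen$compendium
  write_tsv(pathways_long(comp$pathways), file.path(out_dir, "pathways.tsv"))
  for (s in comp$interaction_sources) {
    a <- comp$annotations
    a <- a[a$source_db == s, c("gene_a", "gene_b", "direction", "sign",
                               "mechanism", "dataset"), drop = FALSE]
    write_tsv(a, file.path(out_dir, sprintf("interactions_%s.tsv", s)))
  }
  write_tsv(comp$genes[, c("gene_id", "alt_id", "function_category")],
            file.path(out_dir, "gene_annotations.tsv"))
  truth <- gen$truth
  truth$intermediates <- truth$intermediates  # data frames serialize as records
  jsonlite::write_json(unclass(truth), file.path(out_dir, "planted_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  cfg <- gen$config
  cfg$scaffold <- cfg$scaffold
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "generator_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(gen)
}

manifest_of <- function(out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  data.frame(file = files, md5 = unname(sums), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes build, topology, similarity, concordance, modularity and path
#' stages in order (disabled stages skipped), writing machine-readable
#' outputs plus a checksum manifest under `out_dir`. The effective
#' configuration is echoed verbatim into the output directory; identical
#' configuration and seed give identical manifest checksums. Downstream
#' stages are pure consumers: the compendium files are written once by the
#' build stage and never modified.
#'
#' @param config a `run_config` (see [pipeline_config()]) or path to its
#'   JSON serialization.
#' @param out_dir output directory.
#' @return The run report (stages run, manifest), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stages <- config$stages %||% list()
  params <- config$params %||% list()
  seed <- params$seed %||% 1L
  report <- list(stages_run = character(0))

  run_stage <- function(name, fn) {
    ok <- tryCatch({ fn(); TRUE }, error = function(e) {
      stop_format("stage '%s' failed: %s", name, conditionMessage(e))
    })
    report$stages_run <<- c(report$stages_run, name)
  }

  comp <- NULL
  run_stage("build", function() {
    comp <<- if (!is.null(config$inputs)) {
      load_inputs(config$inputs)
    } else {
      sim <- config$simulate %||% list()
      cfg <- do.call(synthetic_config, sim)
      gen <- if (!is.null(cfg$scaffold)) generate_scaffold_network(cfg) else
        generate_compendium(cfg)
      dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
      jsonlite::write_json(unclass(gen$truth),
                           file.path(out_dir, "truth", "planted_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null", dataframe = "rows")
      gen$compendium
    }
    write_compendium(comp, file.path(out_dir, "compendium"))
  })

  if (isTRUE(stages$topology)) run_stage("topology", function() {
    d <- compute_degrees(comp)
    bt <- compute_betweenness(comp)
    g <- comp$genes
    g$betweenness <- unname(bt[g$gene_id])
    write_tsv(g, file.path(out_dir, "gene_metrics.tsv"))
    jsonlite::write_json(d$summary, file.path(out_dir, "degree_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (scan in params$enrichment %||% list()) {
      es <- enrichment_scan(comp, scan$region, scan$category,
                            n_windows = scan$n_windows %||% 50L)
      write_tsv(as.data.frame(es),
                file.path(out_dir, sprintf("enrichment_%s_%s.tsv",
                                           scan$region,
                                           gsub("\\W+", "_", scan$category))))
    }
  })

  if (isTRUE(stages$similarity)) run_stage("similarity", function() {
    sm <- similarity_matrix(comp)
    m <- as.data.frame(sm$values)
    write_tsv(cbind(pathway = rownames(sm$values), m),
              file.path(out_dir, "pathway_similarity.tsv"))
    writeLines(rownames(sm$values)[sm$leaf_order],
               file.path(out_dir, "pathway_similarity_leaf_order.txt"))
  })

  if (isTRUE(stages$concordance)) run_stage("concordance", function() {
    write_tsv(edge_weight_distribution(comp),
              file.path(out_dir, "edge_weight_distribution.tsv"))
    if (length(comp$interaction_sources) >= 2) {
      cm <- consistency_matrix(comp)
      write_tsv(cbind(db = rownames(cm$values), as.data.frame(cm$values)),
                file.path(out_dir, "edge_consistency.tsv"))
    }
  })

  if (isTRUE(stages$modularity)) run_stage("modularity", function() {
    res <- modularity_scores(comp,
                             n_randomizations = params$n_randomizations %||% 100L,
                             seed = seed)
    write_tsv(as.data.frame(res), file.path(out_dir, "modularity.tsv"))
    mm <- modularity_matrix(comp,
                            n_randomizations = params$n_randomizations %||% 100L,
                            seed = seed)
    write_tsv(cbind(network = rownames(mm$m), as.data.frame(mm$m)),
              file.path(out_dir, "modularity_matrix.tsv"))
    write_tsv(cbind(network = rownames(mm$p), as.data.frame(mm$p)),
              file.path(out_dir, "modularity_pvalues.tsv"))
  })

  if (isTRUE(stages$paths)) run_stage("paths", function() {
    dv <- directed_view(comp)
    out <- lapply(params$queries %||% list(), function(q) {
      pe <- enumerate_paths(dv, q$source, q$target,
                            max_length = q$max_length %||% 8L,
                            required_node = q$required_node)
      list(source = q$source, target = q$target,
           counts_by_length = as.numeric(pe$counts_by_length),
           cumulative_counts = as.numeric(pe$cumulative_counts),
           shortest_length = pe$shortest_length,
           through_fraction = pe$through_fraction,
           truncated = pe$truncated)
    })
    jsonlite::write_json(out, file.path(out_dir, "path_queries.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    if (!is.null(params$scaffold_chain)) {
      se <- expand_scaffold(dv, params$scaffold_chain)
      write_tsv(as.data.frame(se), file.path(out_dir, "scaffold_expansion.tsv"))
      sub <- unique(rbind(
        data.frame(from = params$scaffold_chain[-length(params$scaffold_chain)],
                   to = params$scaffold_chain[-1], stringsAsFactors = FALSE),
        se[, c("from", "to")],
        data.frame(from = se$from, to = se$gene, stringsAsFactors = FALSE),
        data.frame(from = se$gene, to = se$to, stringsAsFactors = FALSE)))
      writeLines(sprintf("%s\tdirected\t%s", sub$from, sub$to),
                 file.path(out_dir, "scaffold_expanded.sif"))
    }
  })

  manifest <- manifest_of(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE, digits = NA, dataframe = "rows")
  report$manifest <- manifest
  invisible(report)
}
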