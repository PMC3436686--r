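#' Configuration for the synthetic compendium generator
#'
#' The generator emulates the statistical structure of multi-source pathway
#' and interaction compendia: several pathway databases with overlapping,
#' power-law-multiplicity gene memberships; several interaction databases
#' with controllable pairwise edge sharing (yielding a heavy-tailed edge
#' weight distribution); a tunable within-pathway edge enrichment (the
#' planted modularity); and mixed directed/undirected, signed/unsigned
#' edges. All randomness flows from the single `seed`.
#'
#' @param n_genes number of genes; every gene is placed in at least one
#'   pathway, so this is also the master-list size.
#' @param pathway_sources named integer vector: pathways per pathway
#'   database.
#' @param interaction_sources character vector of interaction database
#'   names.
#' @param pathway_size_range integer `c(min, max)`; `NULL` (default) centres
#'   the range on the membership capacity implied by the multiplicity
#'   distribution.
#' @param membership_exponent,membership_cap per-gene pathway multiplicity
#'   (Pathway Maps) is drawn from a truncated discrete power law
#'   `P(m) ~ m^-exponent`, `m = 1..cap`. Exponent 2 reproduces the regime
#'   in which most genes are pathway-specific.
#' @param n_edges_per_source distinct gene pairs generated per interaction
#'   source (before sharing).
#' @param internal_edge_enrichment planted within-pathway edge enrichment;
#'   1 = random. Interpretation depends on `enrichment_mode`.
#' @param enrichment_mode `"fold_vs_null"` (default): the value is the
#'   target fold-enrichment of a pathway's internal-edge fraction relative
#'   to the membership-randomization null, planted via an analytically
#'   calibrated acceptance ratio (see the methods vignette);
#'   `"propensity"`: the value is used directly as the acceptance odds for
#'   within-pathway pairs; `"fold_vs_uniform"`: the internal edge count is
#'   the value times its uniform-random-placement expectation.
#' @param source_sharing probability that an edge generated in one source is
#'   copied into each other source; small values give the heavy-tailed,
#'   mostly single-source edge weight distribution seen in real compendia.
#' @param directed_fraction fraction of source annotations that are directed
#'   (split evenly between forward and reverse).
#' @param sign_fractions,mechanism_fractions named length-3 probability
#'   vectors over (positive, negative, unsigned) and (direct, indirect,
#'   unknown).
#' @param function_categories named probability vector used to annotate
#'   genes with function categories.
#' @param n_meta_datasets if > 0, the first interaction source is treated as
#'   a meta-database: each of its edges carries 1 or more per-dataset
#'   sub-annotations (dataset multiplicity `1 + Binomial(n - 1,
#'   source_sharing)`).
#' @param scaffold optional list describing a planted linear signalling
#'   scaffold; see [generate_scaffold_network()].
#' @param seed integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500L,
                             pathway_sources = c(pathdbA = 10L, pathdbB = 10L),
                             interaction_sources = c("intdbA", "intdbB", "intdbC"),
                             pathway_size_range = NULL,
                             membership_exponent = 2,
                             membership_cap = 10L,
                             n_edges_per_source = 1000L,
                             internal_edge_enrichment = 1,
                             enrichment_mode = c("fold_vs_null", "propensity",
                                                 "fold_vs_uniform"),
                             source_sharing = 0.1,
                             directed_fraction = 0.5,
                             sign_fractions = c(positive = 0.45,
                                                negative = 0.25,
                                                unsigned = 0.30),
                             mechanism_fractions = c(direct = 0.5,
                                                     indirect = 0.3,
                                                     unknown = 0.2),
                             function_categories = c("Protein kinase" = 0.12,
                                                     "Transcription factor" = 0.12,
                                                     "Generic binding protein" = 0.26,
                                                     other = 0.50),
                             n_meta_datasets = 0L,
                             scaffold = NULL,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              pathway_sources = pathway_sources,
              interaction_sources = as.character(interaction_sources),
              pathway_size_range = pathway_size_range,
              membership_exponent = membership_exponent,
              membership_cap = as.integer(membership_cap),
              n_edges_per_source = as.integer(n_edges_per_source),
              internal_edge_enrichment = internal_edge_enrichment,
              enrichment_mode = match.arg(enrichment_mode),
              source_sharing = source_sharing,
              directed_fraction = directed_fraction,
              sign_fractions = sign_fractions,
              mechanism_fractions = mechanism_fractions,
              function_categories = function_categories,
              n_meta_datasets = as.integer(n_meta_datasets),
              scaffold = scaffold,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  assert_that(cfg$n_genes >= 10L, "n_genes must be at least 10")
  assert_that(length(cfg$pathway_sources) >= 1L &&
                !is.null(names(cfg$pathway_sources)),
              "pathway_sources must be a named vector of pathway counts")
  assert_that(length(cfg$interaction_sources) >= 1L,
              "at least one interaction source is required")
  n_pw <- sum(cfg$pathway_sources)
  assert_that(n_pw >= 1L, "at least one pathway is required")
  assert_that(cfg$membership_exponent > 0, "membership_exponent must be > 0")
  assert_that(cfg$membership_cap >= 1L, "membership_cap must be >= 1")
  max_pairs <- choose(cfg$n_genes, 2)
  assert_that(cfg$n_edges_per_source <= max_pairs,
              "n_edges_per_source (%d) exceeds the %d possible gene pairs",
              cfg$n_edges_per_source, max_pairs)
  assert_that(cfg$internal_edge_enrichment >= 0,
              "internal_edge_enrichment must be >= 0")
  for (p in c("source_sharing", "directed_fraction")) {
    assert_that(cfg[[p]] >= 0 && cfg[[p]] <= 1, "%s must be in [0, 1]", p)
  }
  for (f in c("sign_fractions", "mechanism_fractions",
              "function_categories")) {
    assert_that(all(cfg[[f]] >= 0) && abs(sum(cfg[[f]]) - 1) < 1e-8,
                "%s must be non-negative and sum to 1", f)
  }
  if (!is.null(cfg$pathway_size_range)) {
    r <- cfg$pathway_size_range
    assert_that(length(r) == 2L && r[1] >= 2 && r[2] >= r[1] &&
                  r[2] <= cfg$n_genes,
                "pathway_size_range must be c(min >= 2, max <= n_genes)")
    assert_that(n_pw * r[2] >= cfg$n_genes,
                "pathway capacity too small: every gene needs a pathway")
  }
  if (!is.null(cfg$scaffold)) {
    sc <- cfg$scaffold
    assert_that(length(sc$chain) >= 3L, "scaffold chain length must be >= 3")
    assert_that(!anyDuplicated(sc$chain), "scaffold chain genes must be distinct")
    k <- length(sc$chain)
    assert_that((sc$n_bypass %||% 0L) <= k - 2L,
                "n_bypass exceeds the %d chain positions that skip node 2", k - 2L)
    assert_that((sc$n_intermediates %||% 0L) <= k * (k - 1L),
                "n_intermediates exceeds the available ordered scaffold pairs")
  }
  structure(cfg, class = c("synthetic_config", "list"))
}

# truncated discrete power-law sampler for Pathway Maps
sample_multiplicity <- function(n, exponent, cap) {
  m <- seq_len(cap)
  p <- m^(-exponent)
  sample(m, n, replace = TRUE, prob = p / sum(p))
}

# memberships: per-gene multiplicity and per-pathway sizes reconciled to a
# common capacity, then stub-matched with duplicate repair
generate_memberships <- function(cfg, gene_ids) {
  n <- length(gene_ids)
  n_pw <- sum(cfg$pathway_sources)
  cap <- min(cfg$membership_cap, n_pw)
  maps <- sample_multiplicity(n, cfg$membership_exponent, cap)
  size_range <- cfg$pathway_size_range
  if (is.null(size_range)) {
    mean_size <- max(3, round(sum(maps) / n_pw))
    size_range <- c(max(2L, mean_size - max(2L, round(0.3 * mean_size))),
                    min(n, mean_size + max(2L, round(0.3 * mean_size))))
  }
  sizes <- sample(seq.int(size_range[1], size_range[2]), n_pw, replace = TRUE)
  # keep the drawn sizes feasible: total capacity must cover every gene once
  # (maps >= 1) and cannot exceed n_genes * cap memberships
  for (guard in seq_len(10L * n_pw)) {
    if (sum(sizes) >= n && sum(sizes) <= n * cap) break
    if (sum(sizes) < n) {
      i <- which.min(sizes)
      if (sizes[i] >= size_range[2]) break
      sizes[i] <- sizes[i] + 1L
    } else {
      i <- which.max(sizes)
      if (sizes[i] <= size_range[1]) break
      sizes[i] <- sizes[i] - 1L
    }
  }
  assert_that(sum(sizes) >= n && sum(sizes) <= n * cap,
              "infeasible config: pathway capacity cannot cover %d genes", n)
  # reconcile total membership with total pathway capacity
  for (iter in seq_len(50L * n)) {
    delta <- sum(maps) - sum(sizes)
    if (delta == 0L) break
    if (delta > 0L) {
      i <- sample.int(n, 1L)
      if (maps[i] > 1L) maps[i] <- maps[i] - 1L
    } else {
      i <- sample.int(n, 1L)
      if (maps[i] < cap) maps[i] <- maps[i] + 1L
    }
  }
  assert_that(sum(maps) == sum(sizes),
              "infeasible config: cannot reconcile membership multiplicity with pathway sizes")
  inc_g <- sample(rep.int(seq_len(n), maps))
  inc_p <- sample(rep.int(seq_len(n_pw), sizes))
  # repair duplicate (pathway, gene) incidences by random swaps
  for (attempt in seq_len(200L * length(inc_g))) {
    dup <- duplicated(paste(inc_p, inc_g))
    if (!any(dup)) break
    k <- which(dup)[1L]
    j <- sample.int(length(inc_g), 1L)
    tmp <- inc_g[k]; inc_g[k] <- inc_g[j]; inc_g[j] <- tmp
  }
  dup <- duplicated(paste(inc_p, inc_g))
  if (any(dup)) { # extremely dense configs: drop the stragglers
    inc_p <- inc_p[!dup]; inc_g <- inc_g[!dup]
  }
  memb <- matrix(FALSE, n_pw, n, dimnames = list(NULL, gene_ids))
  memb[cbind(inc_p, inc_g)] <- TRUE
  db <- rep(names(cfg$pathway_sources), cfg$pathway_sources)
  labels <- unlist(lapply(cfg$pathway_sources, function(k) {
    sprintf("PW%02d", seq_len(k))
  }), use.names = FALSE)
  pw <- pathway_table(paste(db, labels, sep = "_"), db,
                      lapply(seq_len(n_pw), function(i) gene_ids[memb[i, ]]))
  list(pathways = pw, memb = memb)
}

# closed-form fold-enrichment of the mean per-pathway internal fraction over
# the multiplicity-weighted null, evaluated on a realized edge set; used to
# calibrate the planting so that fold_vs_null is met in expectation
planted_fold <- function(memb, ea, eb) {
  n <- ncol(memb)
  maps <- colSums(memb)
  sizes <- rowSums(memb)
  t_inc <- sum(maps)
  w2 <- (t_inc^2 - sum(maps^2)) / 2
  deg <- tabulate(c(ea, eb), n)
  edge_w <- sum(maps[ea] * maps[eb])
  mdeg <- sum(maps * deg)
  internal <- memb[, ea, drop = FALSE] & memb[, eb, drop = FALSE]
  p_in <- 2 * rowSums(internal)
  p_t <- as.numeric(memb %*% deg)
  obs <- ifelse(p_t > 0, p_in / p_t, NA_real_)
  e_in <- sizes * (sizes - 1) / 2 / w2 * edge_w
  e_t <- sizes / t_inc * mdeg
  null <- 2 * e_in / e_t
  mean(obs / null, na.rm = TRUE)
}

# analytic first guess for the acceptance odds under fold_vs_null
analytic_odds <- function(memb, fold) {
  n <- ncol(memb)
  maps <- colSums(memb)
  sizes <- rowSums(memb)
  co <- crossprod(memb) > 0
  diag(co) <- FALSE
  cg <- colSums(co)
  mw_tot <- sum(maps)^2 - sum(maps^2)
  pi_mw <- sum((outer(maps, maps) * co)) / mw_tot
  mean_fold <- function(w) {
    deg <- (n - 1) + (w - 1) * cg
    obs <- vapply(seq_len(nrow(memb)), function(p) {
      s <- sizes[p]
      s * (s - 1) * w / sum(deg[memb[p, ]])
    }, numeric(1))
    dnull <- 1 + (w - 1) * pi_mw
    degw <- sum(maps * deg) / sum(maps)
    null <- (sizes - 1) * dnull / degw
    mean(obs / null, na.rm = TRUE)
  }
  lo <- 1e-6; hi <- 500
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean_fold(mid) < fold) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# sample n_edges distinct canonical pairs; within-pathway pairs accepted at
# odds `w` relative to other pairs
sample_edge_pairs <- function(n_genes, n_edges, co, w) {
  acc_in <- if (w >= 1) 1 else w
  acc_out <- if (w >= 1) 1 / w else 1
  if (w == 0) { acc_in <- 0; acc_out <- 1 }
  seen <- character(0)
  ea <- integer(0); eb <- integer(0)
  for (round in 1:200) {
    need <- n_edges - length(ea)
    if (need <= 0L) break
    b <- max(4L * need, 200L)
    x <- sample.int(n_genes, b, replace = TRUE)
    y <- sample.int(n_genes, b, replace = TRUE)
    ok <- x != y
    x <- x[ok]; y <- y[ok]
    sw <- x > y
    a1 <- ifelse(sw, y, x); b1 <- ifelse(sw, x, y)
    internal <- co[cbind(a1, b1)]
    keep <- runif(length(a1)) < ifelse(internal, acc_in, acc_out)
    a1 <- a1[keep]; b1 <- b1[keep]
    key <- paste(a1, b1)
    new <- !duplicated(key) & !(key %in% seen)
    a1 <- a1[new]; b1 <- b1[new]
    take <- seq_len(min(need, length(a1)))
    ea <- c(ea, a1[take]); eb <- c(eb, b1[take])
    seen <- c(seen, paste(a1[take], b1[take]))
  }
  assert_that(length(ea) == n_edges,
              "could not place %d edges; config too dense or enrichment degenerate",
              n_edges)
  list(a = ea, b = eb)
}

# per-source edge sets: originals plus independent Bernoulli copies into the
# other sources (the sharing model behind the heavy-tailed edge weights)
generate_source_edges <- function(cfg, co) {
  ns <- length(cfg$interaction_sources)
  w <- attr(co, "acceptance_odds")
  orig <- lapply(seq_len(ns), function(s) {
    sample_edge_pairs(ncol(co), cfg$n_edges_per_source, co, w)
  })
  per_source <- lapply(seq_len(ns), function(s) {
    a <- orig[[s]]$a; b <- orig[[s]]$b
    for (t in seq_len(ns)) {
      if (t == s) next
      copy <- runif(length(orig[[t]]$a)) < cfg$source_sharing
      a <- c(a, orig[[t]]$a[copy]); b <- c(b, orig[[t]]$b[copy])
    }
    key <- paste(a, b)
    keep <- !duplicated(key)
    list(a = a[keep], b = b[keep])
  })
  names(per_source) <- cfg$interaction_sources
  per_source
}

sample_from <- function(fractions, n) {
  sample(names(fractions), n, replace = TRUE, prob = fractions)
}

annotate_source_edges <- function(cfg, per_source, gene_ids) {
  out <- lapply(names(per_source), function(s) {
    es <- per_source[[s]]
    n <- length(es$a)
    if (n == 0L) return(empty_interactions())
    directed <- runif(n) < cfg$directed_fraction
    direction <- ifelse(directed,
                        ifelse(runif(n) < 0.5, "forward", "reverse"),
                        "undirected")
    rec <- data.frame(gene_a = gene_ids[es$a], gene_b = gene_ids[es$b],
                      direction = direction,
                      sign = sample_from(cfg$sign_fractions, n),
                      mechanism = sample_from(cfg$mechanism_fractions, n),
                      raw_relation = NA_character_,
                      dataset = NA_character_, source_db = s,
                      stringsAsFactors = FALSE)
    if (s == names(per_source)[1] && cfg$n_meta_datasets > 0L) {
      # meta-database: replicate each edge into >= 1 dataset sub-annotations
      k <- 1L + rbinom(n, cfg$n_meta_datasets - 1L, cfg$source_sharing)
      rec <- rec[rep(seq_len(n), k), , drop = FALSE]
      rec$dataset <- unlist(lapply(k, function(ki) {
        paste0("DS", sample.int(cfg$n_meta_datasets, ki))
      }))
      rownames(rec) <- NULL
    }
    rec
  })
  out
}

#' Generate a synthetic compendium with planted ground truth
#'
#' Deterministic given `config$seed`. The returned truth records, per
#' pathway, the realized internal-edge fraction and the planted modularity
#' target, along with the generator's calibrated acceptance odds.
#'
#' @param config a [synthetic_config()].
#' @return A list with elements `compendium` (a validated [compendium]) and
#'   `truth` (a `planted_truth` list).
#' @export
generate_compendium <- function(config) {
  config <- validate_synthetic_config(config)
  withr::with_seed(config$seed, generate_compendium_impl(config))
}

generate_compendium_impl <- function(cfg) {
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  mem <- generate_memberships(cfg, gene_ids)
  co <- crossprod(mem$memb) > 0
  diag(co) <- FALSE
  e <- cfg$internal_edge_enrichment
  pi_pair <- sum(co) / (cfg$n_genes * (cfg$n_genes - 1))
  w <- switch(cfg$enrichment_mode,
    propensity = e,
    fold_vs_uniform = {
      assert_that(e * pi_pair < 1,
                  "fold_vs_uniform enrichment infeasible: e * internal pair fraction >= 1")
      if (e == 0) 0 else e * (1 - pi_pair) / (1 - e * pi_pair)
    },
    fold_vs_null = {
      if (e == 1) 1 else if (e == 0) 0 else analytic_odds(mem$memb, e)
    }
  )
  attr(co, "acceptance_odds") <- w
  per_source <- generate_source_edges(cfg, co)
  if (cfg$enrichment_mode == "fold_vs_null" && !e %in% c(0, 1)) {
    # refine the acceptance odds until the realized ensemble edge set carries
    # the target fold-enrichment over the closed-form null (kept edge set =
    # best pass); deterministic given the seed
    best <- list(fold = Inf, per_source = per_source, w = w)
    for (pass in 1:8) {
      pooled <- unique(do.call(rbind, lapply(per_source, function(x) {
        cbind(x$a, x$b)
      })))
      fold <- planted_fold(mem$memb, pooled[, 1], pooled[, 2])
      if (is.finite(fold) && abs(fold - e) < abs(best$fold - e)) {
        best <- list(fold = fold, per_source = per_source, w = w)
      }
      if (!is.finite(fold) || fold <= 1 || abs(fold - e) < 0.01) break
      w <- 1 + (w - 1) * (e - 1) / (fold - 1)
      attr(co, "acceptance_odds") <- w
      per_source <- generate_source_edges(cfg, co)
    }
    per_source <- best$per_source
    w <- best$w
  }
  batches <- annotate_source_edges(cfg, per_source, gene_ids)
  gene_ann <- data.frame(
    gene_id = gene_ids,
    alt_id = sprintf("ALT:%s", gene_ids),
    function_category = sample_from(cfg$function_categories, cfg$n_genes),
    stringsAsFactors = FALSE
  )
  comp <- build_ensemble(mem$pathways, batches, gene_annotations = gene_ann)
  conn <- lapply(seq_len(nrow(comp$pathways)), function(i) {
    pathway_connectivity(comp$pathways$genes[[i]], comp$edges)
  })
  truth <- structure(list(
    per_pathway_internal_fraction = setNames(
      vapply(conn, function(x) x$ratio, numeric(1)),
      paste(comp$pathways$pathway_label, comp$pathways$source_db, sep = "|")),
    expected_modularity = if (cfg$enrichment_mode == "propensity") {
      NA_real_
    } else e - 1,
    acceptance_odds = w,
    internal_pair_fraction = pi_pair,
    scaffold_nodes = NULL, bypass_edges = NULL, intermediates = NULL,
    seed = cfg$seed
  ), class = "planted_truth")
  list(compendium = comp, truth = truth, config = cfg)
}

scaffold_class <- function(i, j) {
  ifelse(j == i + 1L, "parallel", ifelse(i < j - 1L, "feed-forward",
                                         "feed-back"))
}

#' Generate a compendium with a planted signalling scaffold
#'
#' Plants a directed linear chain (ligand to sentinel effector), exactly
#' `n_bypass` directed edges from the chain's first node that skip the
#' second node, and `n_intermediates` one-step detours between scaffold node
#' pairs, on top of a synthetic background network. Background edges never
#' point into the scaffold, so the planted elements are exactly the
#' recoverable ones.
#'
#' @param config a [synthetic_config()] whose `scaffold` element is a list
#'   with `chain` (character vector, length >= 3), and optionally `n_bypass`,
#'   `n_intermediates`, `scaffold_sharing` (probability a planted edge is
#'   copied into each additional source; default 0.9) and `n_out_arcs`
#'   (random arcs from non-source scaffold nodes into the background;
#'   default 2 per node).
#' @return A list with `compendium` and `truth`; the truth carries the
#'   scaffold nodes, the planted bypass edges and the planted intermediates
#'   with their loop classification (parallel, feed-forward, feed-back).
#' @export
generate_scaffold_network <- function(config) {
  config <- validate_synthetic_config(config)
  assert_that(!is.null(config$scaffold), "config$scaffold is required")
  withr::with_seed(config$seed, generate_scaffold_impl(config))
}

generate_scaffold_impl <- function(cfg) {
  sc <- cfg$scaffold
  chain <- as.character(sc$chain)
  k <- length(chain)
  n_bypass <- sc$n_bypass %||% 0L
  n_int <- sc$n_intermediates %||% 0L
  share <- sc$scaffold_sharing %||% 0.9
  n_out <- sc$n_out_arcs %||% 2L
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  assert_that(!any(chain %in% gene_ids),
              "scaffold chain labels collide with background gene ids")
  ints <- if (n_int > 0L) sprintf("INT%02d", seq_len(n_int)) else character(0)

  mem <- generate_memberships(cfg, gene_ids)
  co <- crossprod(mem$memb) > 0
  diag(co) <- FALSE
  attr(co, "acceptance_odds") <- cfg$internal_edge_enrichment
  per_source <- generate_source_edges(cfg, co)
  batches <- annotate_source_edges(cfg, per_source, gene_ids)

  planted <- data.frame(from = chain[-k], to = chain[-1],
                        stringsAsFactors = FALSE)
  bypass <- NULL
  if (n_bypass > 0L) {
    targets <- sample(chain[3:k], n_bypass)
    bypass <- data.frame(from = chain[1], to = targets,
                         stringsAsFactors = FALSE)
    planted <- rbind(planted, bypass)
  }
  intermediates <- NULL
  if (n_int > 0L) {
    pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
    pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
    pick <- pairs[sample.int(nrow(pairs), n_int), , drop = FALSE]
    intermediates <- data.frame(
      gene = ints, from = chain[pick$i], to = chain[pick$j],
      from_index = pick$i, to_index = pick$j,
      class = scaffold_class(pick$i, pick$j),
      stringsAsFactors = FALSE
    )
    planted <- rbind(planted,
                     data.frame(from = intermediates$from,
                                to = intermediates$gene,
                                stringsAsFactors = FALSE),
                     data.frame(from = intermediates$gene,
                                to = intermediates$to,
                                stringsAsFactors = FALSE))
  }
  if (n_out > 0L && k > 1L) {
    # arcs out of non-source scaffold nodes into the background; these can
    # never create new source->sink routes or accidental intermediates
    from <- rep(chain[-1], each = n_out)
    to <- gene_ids[sample.int(cfg$n_genes, length(from), replace = TRUE)]
    planted_bg <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  } else planted_bg <- NULL

  plant_rec <- function(d, source_db) {
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    data.frame(gene_a = d$from, gene_b = d$to, direction = "forward",
               sign = "positive", mechanism = "direct",
               raw_relation = "planted", dataset = NA_character_,
               source_db = source_db, stringsAsFactors = FALSE)
  }
  all_planted <- rbind(planted, planted_bg)
  srcs <- cfg$interaction_sources
  planted_batches <- c(list(plant_rec(all_planted, srcs[1])),
                       lapply(srcs[-1], function(s) {
                         keep <- runif(nrow(all_planted)) < share
                         plant_rec(all_planted[keep, , drop = FALSE], s)
                       }))
  planted_batches <- planted_batches[!vapply(planted_batches, is.null,
                                             logical(1))]

  scaffold_pw <- pathway_table("SCAFFOLD", names(cfg$pathway_sources)[1],
                               list(c(chain, ints)))
  gene_all <- c(gene_ids, chain, ints)
  gene_ann <- data.frame(
    gene_id = gene_all, alt_id = sprintf("ALT:%s", gene_all),
    function_category = sample_from(cfg$function_categories,
                                    length(gene_all)),
    stringsAsFactors = FALSE
  )
  comp <- build_ensemble(rbind(mem$pathways, scaffold_pw),
                         c(batches, planted_batches),
                         gene_annotations = gene_ann)
  truth <- structure(list(
    per_pathway_internal_fraction = NULL,
    expected_modularity = NA_real_,
    acceptance_odds = cfg$internal_edge_enrichment,
    internal_pair_fraction = NA_real_,
    scaffold_nodes = chain,
    chain_edges = data.frame(from = chain[-k], to = chain[-1],
                             stringsAsFactors = FALSE),
    bypass_edges = bypass,
    intermediates = intermediates,
    seed = cfg$seed
  ), class = "planted_truth")
  list(compendium = comp, truth = truth, config = cfg)
}
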