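#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions the pipeline is tested under: a
#' sparse scale-free interactome (preferential attachment, a desk-scale
#' stand-in for a ~16k-node/~228k-edge merged human interactome),
#' pathway-sized gene sets (5-40 genes), and a seed list of 150 genes of
#' which a controlled fraction is planted into designated "enriched"
#' pathways so recovery is testable against known ground truth.
#'
#' @param rng_seed Integer seed; one seed drives all generators, with
#'   per-stage sub-streams derived deterministically so regenerating one
#'   stage does not perturb the others.
#' @param n_genes Interactome size (default 2000).
#' @param attachment_edges Edges added per node during preferential
#'   attachment (default 3; mean degree just under 6, matching the sparse
#'   regime of curated physical interactomes).
#' @param n_pathways Number of annotation sets (default 50).
#' @param pathway_size_range Inclusive size range of each set (default
#'   5-40).
#' @param n_seed_genes Total seed-list size (default 150).
#' @param n_enriched_pathways Number of planted (truly enriched) pathways
#'   (default 5).
#' @param enrichment_fraction Fraction of each planted pathway's members
#'   forced into the seed list, in (0, 1] (default 0.6); 0 disables
#'   planting entirely (pure null).
#' @param crosstalk_core If positive, the planted pathways additionally
#'   share a common core of this many genes, guaranteeing cross-talk edges
#'   between them (default 0).
#' @param connector_hub_leaves If positive, a designated hub node gets
#'   this many new leaf terminals attached, making the hub the unique
#'   exact Steiner connector (default 0).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(rng_seed = 1L, n_genes = 2000L,
                             attachment_edges = 3L, n_pathways = 50L,
                             pathway_size_range = c(5L, 40L),
                             n_seed_genes = 150L,
                             n_enriched_pathways = 5L,
                             enrichment_fraction = 0.6,
                             crosstalk_core = 0L,
                             connector_hub_leaves = 0L) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
              attachment_edges = as.integer(attachment_edges),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_seed_genes = as.integer(n_seed_genes),
              n_enriched_pathways = as.integer(n_enriched_pathways),
              enrichment_fraction = enrichment_fraction,
              crosstalk_core = as.integer(crosstalk_core),
              connector_hub_leaves = as.integer(connector_hub_leaves))
  problems <- character(0)
  if (cfg$n_genes < cfg$attachment_edges + 2L)
    problems <- c(problems, "n_genes must exceed attachment_edges + 1")
  if (cfg$n_pathways < 0) problems <- c(problems, "n_pathways must be >= 0")
  if (cfg$n_enriched_pathways > cfg$n_pathways)
    problems <- c(problems, "n_enriched_pathways must be <= n_pathways")
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] > cfg$pathway_size_range[2] ||
      cfg$pathway_size_range[1] < 1L)
    problems <- c(problems, "pathway_size_range must be a valid (min,max)")
  if (cfg$pathway_size_range[2] > cfg$n_genes)
    problems <- c(problems, "pathway sizes must not exceed n_genes")
  if (cfg$enrichment_fraction < 0 || cfg$enrichment_fraction > 1)
    problems <- c(problems, "enrichment_fraction must lie in [0, 1]")
  if (cfg$n_seed_genes > cfg$n_genes)
    problems <- c(problems, "n_seed_genes must not exceed n_genes")
  if (length(problems))
    stop("invalid synthetic_config: ", paste(problems, collapse = "; "))
  structure(cfg, class = "synthetic_config")
}

# deterministic per-stage sub-stream (kept below 2^31)
stage_seed <- function(cfg, stage) {
  offs <- c(interactome = 101L, annotations = 211L, seeds = 307L)
  (cfg$rng_seed %% 1000000L) * 1009L + offs[[stage]]
}

#' Generate a synthetic scale-free interactome
#'
#' Undirected preferential-attachment (Barabasi-Albert) graph over genes
#' `G00001..Gn`, connected by construction, with heavy-tailed degrees.
#' When `connector_hub_leaves > 0`, extra leaf genes `LEAF001..` are
#' attached to the highest-degree node, and recorded as planted Steiner
#' ground truth (the hub is the unique connector of those leaves).
#'
#' @param config A [synthetic_config()].
#' @return List with `net` (igraph) and `truth` (list with
#'   `planted_hub`, `planted_leaves`).
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config, "interactome"))
  g <- sample_pa(config$n_genes, m = config$attachment_edges,
                 directed = FALSE)
  V(g)$name <- sprintf("G%05d", seq_len(config$n_genes))
  g <- interactome(as_edgelist(g)[, 1], as_edgelist(g)[, 2])
  truth <- list(planted_hub = character(0), planted_leaves = character(0))
  if (config$connector_hub_leaves > 0L) {
    hub <- names(which.max(degree(g)))[1]
    leaves <- sprintf("LEAF%03d", seq_len(config$connector_hub_leaves))
    g <- add_vertices(g, length(leaves), name = leaves)
    g <- add_edges(g, as.vector(rbind(match(hub, V(g)$name),
                                      match(leaves, V(g)$name))))
    g <- canonicalize(g)
    truth <- list(planted_hub = hub, planted_leaves = leaves)
  }
  list(net = g, truth = truth)
}

#' Generate synthetic gene-set annotations
#'
#' Samples `n_pathways` sets over the interactome's genes with sizes
#' uniform in `pathway_size_range`. The first `n_enriched_pathways` sets
#' are the designated planted pathways; when `crosstalk_core > 0` they
#' share a common core so the cross-talk builder must recover edges
#' between them.
#'
#' @param config A [synthetic_config()].
#' @param net The interactome from [generate_interactome()].
#' @return List with `collection` (a [gene_set_collection()]) and `truth`
#'   (list with `enriched_pathway_ids`, `core_genes`).
#' @export
generate_annotations <- function(config, net) {
  stopifnot(inherits(config, "synthetic_config"), inherits(net, "igraph"))
  set.seed(stage_seed(config, "annotations"))
  genes <- sort(V(net)$name)
  genes <- genes[!startsWith(genes, "LEAF")]
  lo <- config$pathway_size_range[1]; hi <- config$pathway_size_range[2]
  if (config$n_pathways == 0L)
    return(list(collection = gene_set_collection(list(),
                                                 source_label = "synthetic"),
                truth = list(enriched_pathway_ids = character(0),
                             core_genes = character(0))))
  enriched_ids <- if (config$n_enriched_pathways > 0L)
    sprintf("PW%03d", seq_len(config$n_enriched_pathways)) else character(0)
  core <- character(0)
  if (config$crosstalk_core > 0L && length(enriched_ids))
    core <- sample(genes, config$crosstalk_core)
  sets <- vector("list", config$n_pathways)
  for (i in seq_len(config$n_pathways)) {
    id <- sprintf("PW%03d", i)
    size <- lo + sample.int(hi - lo + 1L, 1L) - 1L  # safe when lo == hi
    if (id %in% enriched_ids && length(core)) {
      extra <- sample(setdiff(genes, core), max(size - length(core), 1L))
      members <- c(core, extra)
    } else {
      members <- sample(genes, size)
    }
    sets[[i]] <- gene_set(id, members, name = paste("synthetic pathway", i))
  }
  list(collection = gene_set_collection(sets, source_label = "synthetic"),
       truth = list(enriched_pathway_ids = enriched_ids, core_genes = core))
}

#' Generate a synthetic seed list with planted enrichment
#'
#' Takes `enrichment_fraction` of each designated enriched pathway's
#' members into the seed list, then fills up to `n_seed_genes` with
#' uniform background genes.
#'
#' @param config A [synthetic_config()].
#' @param annotations Output of [generate_annotations()].
#' @param net The interactome (supplies the gene universe).
#' @return List with `seeds` (a [seed_list()]) and `truth` (list mapping
#'   each planted pathway id to its planted genes).
#' @export
generate_seed_list <- function(config, annotations, net) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(stage_seed(config, "seeds"))
  genes <- sort(V(net)$name)
  genes <- genes[!startsWith(genes, "LEAF")]
  planted <- list()
  picked <- character(0)
  if (config$enrichment_fraction > 0) {
    for (id in annotations$truth$enriched_pathway_ids) {
      m <- annotations$collection$sets[[id]]$members
      take <- max(1L, round(config$enrichment_fraction * length(m)))
      planted[[id]] <- sort(sample(m, take))
      picked <- union(picked, planted[[id]])
    }
  }
  n_bg <- config$n_seed_genes - length(picked)
  if (n_bg < 0L)
    stop("planted seeds exceed n_seed_genes; raise n_seed_genes")
  bg <- sample(setdiff(genes, picked), n_bg)
  list(seeds = seed_list(c(picked, bg), label = "synthetic seeds"),
       truth = list(planted_seed_assignments = planted))
}

#' Run the full synthetic generator and write its files
#'
#' Emits `interactome.tsv`, `annotations.gmt`, `seeds.txt` and
#' `ground_truth.json` under `out_dir`. Byte-identical across runs with
#' the same configuration.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and `truth`.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gi <- generate_interactome(config)
  ga <- generate_annotations(config, gi$net)
  gs <- generate_seed_list(config, ga, gi$net)
  write_interactions(gi$net, file.path(out_dir, "interactome.tsv"))
  if (length(ga$collection$sets))
    write_gmt(ga$collection, file.path(out_dir, "annotations.gmt"))
  writeLines(gs$seeds$genes, file.path(out_dir, "seeds.txt"))
  truth <- c(gi$truth, ga$truth, gs$truth)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(list(net = gi$net, collection = ga$collection,
                 seeds = gs$seeds, truth = truth))
}
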