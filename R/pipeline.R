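#' Assemble and validate a pipeline run configuration
#'
#' Inputs come from one of three sources: `fixtures = TRUE` loads the
#' packaged MDD study tables (and skips the enrichment stage, since the
#' packaged pathway sets are already the enriched, seed-restricted sets);
#' `simulate` takes a [synthetic_config()]; or explicit `seeds_path` /
#' `gmt_path` (+ optional `interactome_path`). Thresholds default to the
#' study's reporting rules: at least 5 seed genes and FDR < 0.05 for
#' enrichment, at least 3 shared genes for a cross-talk edge.
#'
#' @param fixtures Use the packaged MDD fixtures.
#' @param simulate A `synthetic_config`, or `NULL`.
#' @param seeds_path,gmt_path,interactome_path Explicit input files.
#' @param min_seed_genes,fdr_threshold,min_shared Stage thresholds.
#' @param steiner_induce_edges,steiner_forest Steiner flags (see
#'   [approximate_steiner_tree()]).
#' @param out_dir Output directory.
#' @param rng_seed Seed forwarded to the synthetic generator.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fixtures = FALSE, simulate = NULL,
                       seeds_path = NULL, gmt_path = NULL,
                       interactome_path = NULL,
                       min_seed_genes = 5, fdr_threshold = 0.05,
                       min_shared = 3, steiner_induce_edges = FALSE,
                       steiner_forest = FALSE, out_dir = tempfile("mddnet_"),
                       rng_seed = 1L) {
  if (fdr_threshold < 0 || fdr_threshold > 1)
    stop("invalid run_config: fdr_threshold must lie in [0, 1]")
  if (min_seed_genes < 1) stop("invalid run_config: min_seed_genes must be >= 1")
  if (min_shared < 1) stop("invalid run_config: min_shared must be >= 1")
  modes <- c(fixtures, !is.null(simulate), !is.null(seeds_path))
  if (sum(modes) != 1L)
    stop("invalid run_config: choose exactly one of fixtures, simulate, ",
         "or explicit input paths")
  if (!is.null(simulate) && !inherits(simulate, "synthetic_config"))
    stop("invalid run_config: simulate must be a synthetic_config")
  if (!is.null(seeds_path)) {
    if (is.null(gmt_path))
      stop("invalid run_config: gmt_path required with seeds_path")
    for (p in c(seeds_path, gmt_path, interactome_path))
      if (!file.exists(p)) stop("invalid run_config: missing input file ", p)
  }
  structure(list(
    fixtures = fixtures, simulate = simulate, seeds_path = seeds_path,
    gmt_path = gmt_path, interactome_path = interactome_path,
    min_seed_genes = min_seed_genes, fdr_threshold = fdr_threshold,
    min_shared = min_shared, steiner_induce_edges = steiner_induce_edges,
    steiner_forest = steiner_forest, out_dir = out_dir,
    rng_seed = as.integer(rng_seed)), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulate:`
#' mapping is forwarded to [synthetic_config()] (with the top-level
#' `rng_seed` as its default seed).
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    args <- y$simulate
    if (is.null(args$rng_seed) && !is.null(y$rng_seed))
      args$rng_seed <- y$rng_seed
    sim <- do.call(synthetic_config, args)
  }
  keep <- intersect(names(y), setdiff(names(formals(run_config)), "simulate"))
  do.call(run_config, c(y[keep], list(simulate = sim)))
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: input acquisition (fixtures, simulation, or files),
#' enrichment (skipped in fixtures mode, where the packaged sets are
#' pre-filtered), cross-talk network construction, and - when an
#' interactome is available - Steiner subnetwork extraction. Every output
#' file is listed in the returned manifest with an md5 checksum, so a
#' re-run with unchanged inputs is verifiably identical. A stage failure
#' aborts the run, names the stage, and leaves a `.failed` marker in the
#' output directory.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @param quiet Suppress per-stage log lines.
#' @return The run manifest (list): `config` echo, `outputs` (paths +
#'   checksums), `summary` counts. Also written as `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  res <- tryCatch({
    if (config$fixtures) {
      fx <- load_mdd_fixtures()
      seeds <- fx$seeds; collection <- fx$pathways; net <- NULL
      enriched <- collection  # packaged sets are already the enriched ones
      enr_tab <- NULL
      pipeline_log(quiet, stage, "fixtures mode: ", length(seeds$genes),
                   " seeds, ", length(collection$sets), " pathway sets")
    } else if (!is.null(config$simulate)) {
      sim <- simulate_study(config$simulate,
                            file.path(config$out_dir, "simulated"))
      seeds <- sim$seeds; collection <- sim$collection; net <- sim$net
      pipeline_log(quiet, stage, "simulated: ", length(seeds$genes),
                   " seeds, ", length(collection$sets), " sets, ",
                   vcount(net), " interactome nodes")
      enriched <- NULL
    } else {
      seeds <- read_gene_list(config$seeds_path)
      collection <- read_gmt(config$gmt_path)
      net <- if (!is.null(config$interactome_path))
        read_interactions(config$interactome_path) else NULL
      pipeline_log(quiet, stage, "files: ", length(seeds$genes), " seeds, ",
                   length(collection$sets), " sets")
      enriched <- NULL
    }

    outputs <- character(0)
    if (is.null(enriched)) {
      stage <- "enrichment"
      enr_tab <- run_enrichment(seeds, collection,
                                min_seed_genes = config$min_seed_genes,
                                fdr_threshold = config$fdr_threshold)
      keep <- collection$sets[enr_tab$set_id]
      enriched <- if (length(keep))
        gene_set_collection(keep, source_label = "enriched") else
        gene_set_collection(list(), source_label = "enriched")
      p <- file.path(config$out_dir, "enrichment.tsv")
      write_enrichment(enr_tab, p); outputs <- c(outputs, p)
      pipeline_log(quiet, stage, nrow(enr_tab), " of ",
                   length(collection$sets), " sets pass filters")
    }

    stage <- "crosstalk"
    ct <- NULL
    if (length(enriched$sets) >= 2L) {
      ct <- build_crosstalk_network(enriched, min_shared = config$min_shared)
      for (fmt in c("tsv", "sif", "graphml")) {
        p <- file.path(config$out_dir, paste0("crosstalk.", fmt))
        export_network(ct, p, fmt); outputs <- c(outputs, p)
      }
      pipeline_log(quiet, stage, length(ct$nodes), " nodes, ",
                   nrow(ct$edges), " edges")
    } else pipeline_log(quiet, stage, "skipped: fewer than 2 enriched sets")

    stage <- "steiner"
    st <- NULL
    if (!is.null(net) && vcount(net) > 0L) {
      st <- approximate_steiner_tree(
        net, seeds, induce_edges = config$steiner_induce_edges,
        mode = if (config$steiner_forest) "forest" else "largest")
      p <- file.path(config$out_dir, "subnetwork.tsv")
      export_subnetwork(st, p); outputs <- c(outputs, p)
      pc <- file.path(config$out_dir, "connectors.txt")
      writeLines(st$connectors, pc); outputs <- c(outputs, pc)
      pipeline_log(quiet, stage, st$n_nodes, " nodes, ", st$n_edges,
                   " edges, ", length(st$connectors), " connectors")
    } else pipeline_log(quiet, stage, "skipped: no interactome supplied")

    if (!is.null(config$simulate))
      outputs <- c(outputs, file.path(config$out_dir, "simulated",
                                      c("interactome.tsv", "annotations.gmt",
                                        "seeds.txt", "ground_truth.json")))
    manifest <- list(
      config = unclass(config[!(names(config) %in% "simulate")]),
      outputs = lapply(sort(outputs[file.exists(outputs)]), function(p)
        list(path = p, md5 = unname(md5sum(p)))),
      summary = list(
        n_seeds = length(seeds$genes),
        n_sets = length(collection$sets),
        n_enriched = length(enriched$sets),
        crosstalk_nodes = if (is.null(ct)) 0L else length(ct$nodes),
        crosstalk_edges = if (is.null(ct)) 0L else nrow(ct$edges),
        subnetwork_nodes = if (is.null(st)) 0L else st$n_nodes,
        subnetwork_edges = if (is.null(st)) 0L else st$n_edges,
        n_connectors = if (is.null(st)) 0L else length(st$connectors)))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "run.failed"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
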