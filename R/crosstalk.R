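#' Jaccard coefficient of two gene sets
#'
#' `|A intersect B| / |A union B|`.
#'
#' @param a,b [gene_set()] objects.
#' @return A ratio in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  check_pair(a, b)
  length(intersect(a$members, b$members)) /
    length(union(a$members, b$members))
}

#' Overlap coefficient of two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`; 1 whenever one set contains the
#' other, which makes it less size-biased than Jaccard for nested sets.
#'
#' @inheritParams jaccard
#' @return A ratio in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  check_pair(a, b)
  length(intersect(a$members, b$members)) /
    min(length(a$members), length(b$members))
}

#' Cross-talk score of two gene sets
#'
#' Arithmetic mean of the Jaccard and Overlap coefficients; used to rank
#' pathway pairs by the strength of their shared seed-gene content.
#'
#' @inheritParams jaccard
#' @return A ratio in `[0, 1]`, between the two coefficients.
#' @export
crosstalk_score <- function(a, b) {
  (jaccard(a, b) + overlap_coefficient(a, b)) / 2
}

check_pair <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (length(a$members) == 0L || length(b$members) == 0L)
    stop("gene sets must be non-empty")
  invisible(TRUE)
}

#' Build a pathway cross-talk network
#'
#' Evaluates every unordered pair of sets in the collection and connects
#' two sets when they share at least `min_shared` genes (default 3, the
#' study's rule for calling a pathway pair biologically correlated). Edges
#' carry the shared genes, the Jaccard and Overlap coefficients and their
#' mean, and are sorted by descending score (ties by the canonical pair
#' ids). Sets that gain no edge are dropped from the node list, so the
#' network's nodes are exactly the pathways that cross-talk with at least
#' one other.
#'
#' @param collection A [gene_set_collection()] with at least two sets.
#' @param min_shared Minimum shared-gene count for an edge (default 3).
#' @param min_score Optional additional cutoff on the mean coefficient;
#'   `NULL` (default) applies no score filter, matching the study's
#'   definition in which the coefficients only weight and rank edges.
#' @return An object of class `crosstalk_network`: list with `nodes`
#'   (character vector of set ids) and `edges` (data.frame `set_a`,
#'   `set_b`, `n_shared`, `jaccard`, `overlap`, `score`, `shared_genes`,
#'   with `set_a < set_b` lexicographically).
#' @examples
#' fx <- load_mdd_fixtures()
#' net <- build_crosstalk_network(fx$pathways)
#' c(length(net$nodes), nrow(net$edges))
#' @export
build_crosstalk_network <- function(collection, min_shared = 3,
                                    min_score = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) < 2L) stop("collection must have >= 2 sets")
  if (min_shared < 1) stop("min_shared must be >= 1")
  sets <- collection$sets
  ids <- names(sets)
  n <- length(sets)
  members <- lapply(sets, `[[`, "members")
  sizes <- lengths(members)
  npair <- n * (n - 1L) / 2L
  set_a <- set_b <- shared_genes <- character(npair)
  n_shared <- integer(npair)
  ja <- ov <- numeric(npair)
  r <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      shared <- members[[i]][members[[i]] %in% members[[j]]]
      if (length(shared) < min_shared) next
      r <- r + 1L
      pair <- sort(c(ids[i], ids[j]))
      set_a[r] <- pair[1]; set_b[r] <- pair[2]
      n_shared[r] <- length(shared)
      ja[r] <- length(shared) / (sizes[i] + sizes[j] - length(shared))
      ov[r] <- length(shared) / min(sizes[i], sizes[j])
      shared_genes[r] <- paste(shared, collapse = ",")
    }
  }
  keep <- seq_len(r)
  edges <- data.frame(
    set_a = set_a[keep], set_b = set_b[keep], n_shared = n_shared[keep],
    jaccard = ja[keep], overlap = ov[keep],
    score = (ja[keep] + ov[keep]) / 2, shared_genes = shared_genes[keep],
    stringsAsFactors = FALSE)
  if (!is.null(min_score))
    edges <- edges[edges$score >= min_score, , drop = FALSE]
  edges <- edges[order(-edges$score, edges$set_a, edges$set_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodes <- ids[ids %in% c(edges$set_a, edges$set_b)]
  structure(list(nodes = nodes, edges = edges), class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat("<crosstalk_network>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Convert a cross-talk network to an igraph object
#'
#' Edge attributes `n_shared`, `jaccard`, `overlap`, `score` are carried
#' over; isolated sets are (by construction) absent.
#'
#' @param net A `crosstalk_network`.
#' @return An undirected [igraph::igraph] graph.
#' @export
crosstalk_igraph <- function(net) {
  stopifnot(inherits(net, "crosstalk_network"))
  if (nrow(net$edges) == 0L)
    return(make_empty_graph(0, directed = FALSE))
  g <- graph_from_data_frame(
    net$edges[, c("set_a", "set_b", "n_shared", "jaccard", "overlap",
                  "score")],
    directed = FALSE, vertices = data.frame(name = net$nodes))
  g
}

#' Export a cross-talk network
#'
#' @param net A `crosstalk_network`.
#' @param path Output file path.
#' @param format `"tsv"` (edge table with coefficients and shared genes),
#'   `"sif"` (Cytoscape simple interaction format, interaction label
#'   `crosstalk`) or `"graphml"` (edge attributes `n_shared`, `jaccard`,
#'   `overlap`, `score`).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "crosstalk_network"))
  format <- match.arg(format)
  switch(format,
    tsv = write.table(net$edges, path, sep = "\t", quote = FALSE,
                      row.names = FALSE),
    sif = writeLines(
      if (nrow(net$edges)) paste(net$edges$set_a, "crosstalk",
                                 net$edges$set_b) else character(0),
      path),
    graphml = write_graph(crosstalk_igraph(net), path, format = "graphml"))
  invisible(path)
}
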