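#' Approximate Steiner minimal tree connecting seed genes
#'
#' Extracts a disease-specific subnetwork: the smallest tree (approximately)
#' in the interactome that spans the seed genes, introducing as few
#' non-seed "connector" genes as possible. Uses the classical
#' shortest-path 2-approximation: build the metric closure over the
#' terminals, take its minimum spanning tree, expand each closure edge
#' back into a concrete shortest path, take a spanning tree of the union
#' and repeatedly prune non-terminal leaves. The resulting tree has at
#' most twice the edge count of the optimal Steiner tree.
#'
#' Terminals absent from the interactome, or lying outside the connected
#' component that contains the most terminals, are reported in
#' `unreachable_terminals` rather than treated as fatal: curated disease
#' lists routinely contain genes with no catalogued physical interaction.
#'
#' @param net An igraph interactome (see [interactome()]).
#' @param terminals A [seed_list()] or character vector of seed symbols.
#' @param node_weighted If `TRUE`, minimize introduced non-terminal nodes
#'   more directly by weighting each edge with the number of its
#'   non-terminal endpoints (terminals cost 0, connectors 1); the default
#'   `FALSE` minimizes edge count on the unweighted graph.
#' @param mode `"largest"` (default) connects the terminals of the
#'   component holding the most terminals; `"forest"` builds one tree per
#'   component with at least two terminals and returns their union.
#' @param induce_edges If `TRUE`, the returned `subnetwork` additionally
#'   contains every interactome edge between tree nodes (the tree itself
#'   is always available in field `tree`); the subnetwork is then no
#'   longer acyclic.
#' @return An object of class `steiner_result`: fields `subnetwork`,
#'   `tree` (igraph), `terminals_included`, `connectors`,
#'   `unreachable_terminals` (character vectors), `n_nodes`, `n_edges`
#'   (counts on `subnetwork`).
#' @export
approximate_steiner_tree <- function(net, terminals, node_weighted = FALSE,
                                     mode = c("largest", "forest"),
                                     induce_edges = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "igraph"))
  if (vcount(net) == 0L) stop("interactome is empty")
  terms <- terminal_symbols(terminals)
  absent <- setdiff(terms, V(net)$name)
  if (length(absent))
    warning(length(absent), " terminal(s) absent from the interactome")
  present <- intersect(terms, V(net)$name)
  if (length(present) < 2L)
    stop("nothing to connect: fewer than 2 terminals reachable")
  comp <- components(net)
  tcomp <- comp$membership[present]
  if (mode == "largest") {
    counts <- table(tcomp)
    best <- pick_component(counts, comp, net)
    reach <- present[tcomp == best]
    unreachable <- c(absent, setdiff(present, reach))
    if (length(reach) < 2L) stop("nothing to connect: fewer than 2 terminals reachable")
    sub <- induced_subgraph(net, V(net)$name[comp$membership == best])
    sub <- canonicalize(sub)
    tree <- steiner_core(sub, reach, node_weighted)
  } else {
    comps_with <- unique(tcomp)
    trees <- list()
    reach_all <- character(0)
    for (cc in sort(comps_with)) {
      r <- present[tcomp == cc]
      if (length(r) < 2L) next
      sub <- canonicalize(induced_subgraph(
        net, V(net)$name[comp$membership == cc]))
      trees[[length(trees) + 1L]] <- steiner_core(sub, r, node_weighted)
      reach_all <- c(reach_all, r)
    }
    if (length(trees) == 0L) stop("nothing to connect: fewer than 2 terminals reachable")
    tree <- merge_networks(trees)
    reach <- sort(reach_all)
    unreachable <- c(absent, setdiff(present, reach))
  }
  finalize_steiner(net, tree, reach, unreachable, induce_edges,
                   expect_tree = (mode == "largest"))
}

terminal_symbols <- function(terminals) {
  t <- if (inherits(terminals, "seed_list")) terminals$genes else
    normalize_symbols(terminals)
  if (length(t) == 0L) stop("no terminals supplied")
  sort(t)
}

# component with most terminals; ties -> the one containing the
# lexicographically smallest node name
pick_component <- function(counts, comp, net) {
  mx <- max(counts)
  cand <- as.integer(names(counts)[counts == mx])
  if (length(cand) == 1L) return(cand)
  firsts <- vapply(cand, function(cc)
    min(V(net)$name[comp$membership == cc]), character(1))
  cand[order(firsts)][1]
}

canonicalize <- function(g) {
  nodes <- sort(V(g)$name)
  permute(g, match(V(g)$name, nodes))
}

edge_weights <- function(g, terms, node_weighted) {
  if (!node_weighted) return(rep(1, ecount(g)))
  el <- as_edgelist(g, names = TRUE)
  (!(el[, 1] %in% terms)) + (!(el[, 2] %in% terms))
}

# shortest-path 2-approximation on a connected graph containing all terms
steiner_core <- function(g, terms, node_weighted = FALSE) {
  terms <- sort(terms)
  if (length(terms) == 1L)
    return(induced_subgraph(g, terms))
  w <- edge_weights(g, terms, node_weighted)
  d <- distances(g, v = terms, to = terms, weights = w)
  closure_el <- t(combn(length(terms), 2))
  cg <- make_empty_graph(length(terms), directed = FALSE)
  V(cg)$name <- terms
  cg <- add_edges(cg, t(closure_el))
  E(cg)$weight <- d[closure_el]
  mt <- mst(cg, weights = E(cg)$weight)
  # expand each closure edge into one concrete shortest path
  mel <- as_edgelist(mt, names = TRUE)
  eids <- integer(0)
  for (r in seq_len(nrow(mel))) {
    sp <- shortest_paths(g, from = mel[r, 1], to = mel[r, 2], weights = w,
                         output = "epath")
    eids <- c(eids, as.integer(sp$epath[[1]]))
  }
  h <- subgraph_from_edges(g, unique(eids), delete.vertices = TRUE)
  hw <- edge_weights(h, terms, node_weighted)
  t0 <- mst(h, weights = hw)
  prune_leaves(t0, terms)
}

prune_leaves <- function(tree, terms) {
  repeat {
    leaves <- V(tree)$name[degree(tree) <= 1 & !(V(tree)$name %in% terms)]
    if (length(leaves) == 0L) return(tree)
    tree <- delete_vertices(tree, leaves)
  }
}

finalize_steiner <- function(net, tree, reach, unreachable, induce_edges,
                             expect_tree = TRUE) {
  tree <- canonicalize(tree)
  nodes <- V(tree)$name
  if (expect_tree) {
    stopifnot(ecount(tree) == vcount(tree) - 1L, is_connected(tree),
              all(reach %in% nodes))
  }
  subnetwork <- if (induce_edges) canonicalize(induced_subgraph(net, nodes))
                else tree
  structure(list(
    subnetwork = subnetwork,
    tree = tree,
    terminals_included = sort(intersect(nodes, reach)),
    connectors = sort(setdiff(nodes, reach)),
    unreachable_terminals = sort(unreachable),
    n_nodes = vcount(subnetwork),
    n_edges = ecount(subnetwork)),
    class = "steiner_result")
}

#' @export
print.steiner_result <- function(x, ...) {
  cat("<steiner_result>", x$n_nodes, "nodes,", x$n_edges, "edges;",
      length(x$terminals_included), "terminals,",
      length(x$connectors), "connectors,",
      length(x$unreachable_terminals), "unreachable\n")
  invisible(x)
}

#' Exact minimum Steiner tree by exhaustive search
#'
#' Test oracle for [approximate_steiner_tree()]: enumerates connector
#' subsets in order of increasing size (lexicographic node-set order
#' within a size) and returns the first whose union with the terminals
#' induces a connected subgraph, which yields a minimum-node (equivalently
#' minimum-edge) Steiner tree. Exponential; refuses graphs with more than
#' 16 nodes.
#'
#' @inheritParams approximate_steiner_tree
#' @return A `steiner_result` whose `subnetwork` is an exact minimum
#'   Steiner tree for the terminals of the richest component.
#' @export
brute_force_steiner <- function(net, terminals) {
  stopifnot(inherits(net, "igraph"))
  if (vcount(net) > 16L)
    stop("instance too large for exhaustive search (> 16 nodes); ",
         "use approximate_steiner_tree()")
  terms <- terminal_symbols(terminals)
  absent <- setdiff(terms, V(net)$name)
  present <- intersect(terms, V(net)$name)
  if (length(present) < 2L)
    stop("nothing to connect: fewer than 2 terminals reachable")
  comp <- components(net)
  tcomp <- comp$membership[present]
  counts <- table(tcomp)
  best <- pick_component(counts, comp, net)
  reach <- sort(present[tcomp == best])
  unreachable <- c(absent, setdiff(present, reach))
  if (length(reach) < 2L) stop("nothing to connect: fewer than 2 terminals reachable")
  g <- canonicalize(induced_subgraph(
    net, V(net)$name[comp$membership == best]))
  others <- sort(setdiff(V(g)$name, reach))
  found <- NULL
  for (size in 0:length(others)) {
    if (size == 0L) {
      subs <- list(character(0))
    } else {
      subs <- combn(others, size, simplify = FALSE)
    }
    for (s in subs) {
      cand <- induced_subgraph(g, sort(c(reach, s)))
      if (is_connected(cand)) { found <- cand; break }
    }
    if (!is.null(found)) break
  }
  tree <- mst(canonicalize(found), weights = rep(1, ecount(found)))
  finalize_steiner(net, tree, reach, unreachable, induce_edges = FALSE)
}

#' Connector genes of a Steiner subnetwork
#'
#' The tree nodes that are not seed genes: the "novel" genes the
#' extraction introduced to keep the seeds connected.
#'
#' @param result A `steiner_result`.
#' @param seeds A [seed_list()] or character vector.
#' @return Sorted character vector (equals `result$connectors` when the
#'   same seed list was used for extraction).
#' @export
extract_connectors <- function(result, seeds) {
  stopifnot(inherits(result, "steiner_result"))
  s <- terminal_symbols(seeds)
  sort(setdiff(V(result$tree)$name, s))
}

#' Neighborhood of focus genes and its seed-gene content
#'
#' For a set of focus genes (e.g. high-degree hubs of an extracted
#' subnetwork), collects the focus genes and all their direct interactors
#' and reports what fraction of the non-focus neighbors are seed genes.
#'
#' @param net An igraph interactome (or extracted subnetwork).
#' @param focus Character vector of focus gene symbols; must be nodes of
#'   `net`.
#' @param seeds A [seed_list()] or character vector.
#' @return An object of class `neighborhood_report`: `focus_genes`,
#'   `neighborhood` (induced igraph on focus plus interactors),
#'   `neighbors` (the non-focus interactors), `seed_fraction`. A focus
#'   set with no outside interactors reports `seed_fraction = 0` with a
#'   warning.
#' @export
key_node_neighborhood <- function(net, focus, seeds) {
  stopifnot(inherits(net, "igraph"))
  focus <- normalize_symbols(focus)
  if (length(focus) == 0L) stop("focus set is empty")
  if (!all(focus %in% V(net)$name))
    stop("focus genes absent from network: ",
         paste(setdiff(focus, V(net)$name), collapse = ", "))
  s <- terminal_symbols(seeds)
  nb <- unique(unlist(lapply(focus, function(f)
    V(net)$name[as.integer(neighbors(net, f))])))
  nb <- sort(setdiff(nb, focus))
  frac <- if (length(nb) == 0L) {
    warning("focus genes have no interactors outside the focus set; ",
            "seed_fraction reported as 0")
    0
  } else length(intersect(nb, s)) / length(nb)
  structure(list(
    focus_genes = sort(focus),
    neighborhood = canonicalize(induced_subgraph(net, sort(c(focus, nb)))),
    neighbors = nb,
    seed_fraction = frac),
    class = "neighborhood_report")
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat("<neighborhood_report>", length(x$focus_genes), "focus genes,",
      length(x$neighbors), "interactors; seed fraction",
      sprintf("%.3f", x$seed_fraction), "\n")
  invisible(x)
}

#' Export a Steiner subnetwork
#'
#' Writes the subnetwork with a `role` node attribute distinguishing seed
#' terminals from introduced connectors (mirrored as a third TSV column
#' pair; SIF uses interaction label `pp`).
#'
#' @param result A `steiner_result`.
#' @param path Output file path.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_subnetwork <- function(result, path,
                              format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(result, "steiner_result"))
  format <- match.arg(format)
  g <- result$subnetwork
  role <- ifelse(V(g)$name %in% result$connectors, "connector", "seed")
  g <- set_vertex_attr(g, "role", value = role)
  el <- canonical_edgelist(g)
  switch(format,
    tsv = {
      df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                       role_a = role[match(el[, 1], V(g)$name)],
                       role_b = role[match(el[, 2], V(g)$name)],
                       stringsAsFactors = FALSE)
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    sif = writeLines(if (nrow(el)) paste(el[, 1], "pp", el[, 2])
                     else character(0), path),
    graphml = write_graph(g, path, format = "graphml"))
  invisible(path)
}
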