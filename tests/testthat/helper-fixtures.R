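# shared helpers: tiny graphs, random collections, independent oracles

path_graph <- function(nodes) {
  interactome(nodes[-length(nodes)], nodes[-1])
}

star_graph_named <- function(center, leaves) {
  interactome(rep(center, length(leaves)), leaves)
}

random_collection <- function(n_sets, universe, size_range = c(3, 8)) {
  sets <- lapply(seq_len(n_sets), function(i)
    gene_set(sprintf("S%02d", i),
             sample(universe, sample(size_range[1]:size_range[2], 1))))
  gene_set_collection(sets, source_label = "random")
}

# Erdos-Renyi graph with named nodes, conditioned on being connected
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  interactome(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2])
}

# canonical sorted edge list, for graph equality up to isomorphism-by-name
canonical_el <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(matrix(character(0), ncol = 2))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  cbind(a[o], b[o])
}

# enumeration oracle: P(X >= k) by enumerating every n-subset of an
# N-universe and counting those with >= k members of the designated K-set
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  hits <- colSums(draws <= K)  # K-set = elements 1..K
  mean(hits >= k)
}

# the packaged pathway GMT parsed with nothing but base string ops,
# independent of read_gmt
raw_fixture_sets <- function() {
  path <- system.file("extdata", "mdd_pathways.gmt", package = "mddnet")
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  sets
}
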