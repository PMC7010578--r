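#' Build a clean interactome from an edge table
#'
#' The interactome is a simple undirected [igraph::igraph] over uppercase
#' gene symbols: self-interactions are dropped and duplicate pairs
#' (including reversed order) are collapsed. The counts of records dropped
#' by cleaning are stored as graph attributes `dropped_self` and
#' `dropped_duplicate`.
#'
#' @param from,to Character vectors of interacting gene symbols.
#' @return An undirected simple igraph graph with vertices sorted by name
#'   (a canonical ordering that makes downstream tie-breaking
#'   deterministic).
#' @export
interactome <- function(from, to) {
  stopifnot(length(from) == length(to))
  from <- toupper(trimws(as.character(from)))
  to <- toupper(trimws(as.character(to)))
  keep <- nzchar(from) & nzchar(to)
  from <- from[keep]; to <- to[keep]
  self <- from == to
  a <- pmin(from[!self], to[!self])
  b <- pmax(from[!self], to[!self])
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  el <- cbind(a[!dup], b[!dup])
  if (nrow(el) == 0L) {
    g <- make_empty_graph(0, directed = FALSE)
    g <- set_graph_attr(g, "dropped_self", sum(self))
    g <- set_graph_attr(g, "dropped_duplicate", sum(dup))
    return(g)
  }
  nodes <- sort(unique(c(el)))
  g <- graph_from_edgelist(el, directed = FALSE)
  g <- permute(g, match(V(g)$name, nodes))
  g <- set_graph_attr(g, "dropped_self", sum(self))
  g <- set_graph_attr(g, "dropped_duplicate", sum(dup))
  g
}

#' Read a protein-protein interaction network
#'
#' TSV: first two columns are the interacting symbols, extra columns
#' ignored. SIF: `source<relation>target1 [target2 ...]`, whitespace- or
#' tab-separated; every source-target pair becomes an edge. Cleaning
#' (symbol normalization, self-loop and duplicate removal) is applied as
#' in [interactome()]; a message reports how many records were dropped.
#'
#' @param path Path to the edge list.
#' @param format `"tsv"` or `"sif"`; default guesses from the extension.
#' @return An undirected simple igraph graph; empty file yields an empty
#'   graph with a warning.
#' @export
read_interactions <- function(path, format = c("auto", "tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("interaction file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "tsv"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("no interactions in ", path)
    return(make_empty_graph(0, directed = FALSE))
  }
  if (format == "tsv") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2L)
    if (length(bad))
      stop("malformed interaction line (fewer than 2 columns) at line ",
           bad[1], " of ", path)
    from <- vapply(fields, `[[`, character(1), 1)
    to <- vapply(fields, `[[`, character(1), 2)
  } else {
    fields <- strsplit(lines, "[ \t]+")
    bad <- which(lengths(fields) < 3L)
    if (length(bad))
      stop("malformed SIF line (fewer than 3 fields) at line ", bad[1],
           " of ", path)
    from <- unlist(lapply(fields, function(f) rep(f[1], length(f) - 2L)))
    to <- unlist(lapply(fields, function(f) f[-(1:2)]))
  }
  g <- interactome(from, to)
  ds <- graph_attr(g, "dropped_self"); dd <- graph_attr(g, "dropped_duplicate")
  if (ds + dd > 0)
    message("read_interactions: dropped ", ds, " self-loop(s) and ", dd,
            " duplicate pair(s) from ", basename(path))
  g
}

#' Write an interactome as a two-column TSV edge list
#'
#' Headerless, one interaction per line, edges in canonical sorted order
#' so identical graphs produce byte-identical files; round-trips through
#' [read_interactions()].
#'
#' @param net An igraph interactome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(net, path) {
  el <- canonical_edgelist(net)
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

canonical_edgelist <- function(net) {
  el <- as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L)
    return(matrix(character(0), ncol = 2))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  cbind(a[o], b[o])
}

#' Merge interactomes into one network
#'
#' Node set is the union of node sets, edge set the union of edge sets;
#' cleaning invariants (simple, undirected, no self-loops) are re-asserted
#' on the result. Commutative, associative and idempotent on edge sets.
#'
#' @param nets List of igraph interactomes (length >= 1).
#' @return The merged interactome.
#' @export
merge_networks <- function(nets) {
  if (!is.list(nets) || length(nets) == 0L)
    stop("merge_networks needs a non-empty list of networks")
  stopifnot(all(vapply(nets, inherits, logical(1), "igraph")))
  els <- lapply(nets, as_edgelist, names = TRUE)
  el <- do.call(rbind, els)
  isolated <- sort(unique(unlist(lapply(nets, function(g)
    V(g)$name[degree(g) == 0]))))
  if (nrow(el) == 0L) {
    g <- make_empty_graph(0, directed = FALSE)
    if (length(isolated)) g <- add_vertices(g, length(isolated),
                                            name = isolated)
    return(g)
  }
  g <- interactome(el[, 1], el[, 2])
  lost <- setdiff(isolated, V(g)$name)
  if (length(lost)) g <- add_vertices(g, length(lost), name = lost)
  g
}

#' Degree of every node
#'
#' @param net An igraph interactome.
#' @return Named integer vector of node degrees (sums to twice the edge
#'   count).
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "igraph"))
  if (vcount(net) == 0L) return(setNames(integer(0), character(0)))
  d <- degree(net)
  storage.mode(d) <- "integer"
  d
}
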