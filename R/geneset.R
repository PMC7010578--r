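#' Normalize gene symbols
#'
#' Trims whitespace, uppercases, drops empty strings and collapses
#' duplicates. Gene identity throughout the package is the normalized
#' uppercase symbol string; no remote identifier resolution is performed.
#'
#' @param genes Character vector of gene symbols (any case, possibly padded).
#' @return Character vector of unique, uppercase, whitespace-free symbols,
#'   in first-appearance order. An all-empty input yields `character(0)`.
#' @examples
#' normalize_symbols(c("tp53", " TP53", "Bdnf", ""))
#' @export
normalize_symbols <- function(genes) {
  if (is.null(genes)) return(character(0))
  stopifnot(is.character(genes) | length(genes) == 0)
  g <- toupper(trimws(as.character(genes)))
  g <- g[!is.na(g) & nzchar(g)]
  unique(g)
}

#' Construct a gene set
#'
#' A gene set is a named collection of gene symbols: a pathway or GO term's
#' members, or its restriction to a seed list (as in the packaged pathway
#' fixtures, whose gene columns are the seed genes annotated to each
#' pathway).
#'
#' @param set_id Short identifier string (unique within a collection).
#' @param members Character vector of gene symbols; normalized on input.
#' @param name Display name; defaults to `set_id`.
#' @return An object of class `gene_set` with fields `set_id`, `name`,
#'   `members` (sorted unique uppercase symbols).
#' @export
gene_set <- function(set_id, members, name = set_id) {
  stopifnot(is.character(set_id), length(set_id) == 1L, nzchar(set_id))
  members <- sort(normalize_symbols(members))
  if (length(members) == 0L)
    stop("gene set '", set_id, "' has no members after normalization")
  if (any(grepl("\\s", members)))
    stop("gene symbols must not contain whitespace")
  structure(list(set_id = set_id, name = name, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$set_id, "-", length(x$members), "genes\n")
  cat(" ", paste(head(x$members, 8), collapse = ", "),
      if (length(x$members) > 8) "...", "\n")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets List of [gene_set()] objects with unique `set_id`s.
#' @param source_label Free-text provenance label.
#' @return An object of class `gene_set_collection`: `source_label` plus a
#'   list `sets` named by `set_id`, input order preserved.
#' @export
gene_set_collection <- function(sets, source_label = "unlabelled") {
  stopifnot(is.list(sets))
  ok <- vapply(sets, inherits, logical(1), what = "gene_set")
  if (length(sets) && !all(ok)) stop("all elements must be gene_set objects")
  ids <- vapply(sets, `[[`, character(1), "set_id")
  if (anyDuplicated(ids))
    stop("duplicate set_ids in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(sets) <- ids
  structure(list(source_label = source_label, sets = sets),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", x$source_label, "-", length(x$sets), "sets\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Construct a seed gene list
#'
#' The seed list holds the curated disease-associated genes (the study's
#' candidate-gene compilation); its members are the terminals of subnetwork
#' extraction and the foreground of enrichment testing.
#'
#' @param genes Character vector of gene symbols; normalized on input.
#' @param label Free-text label.
#' @return An object of class `seed_list` with fields `label` and `genes`
#'   (sorted unique uppercase symbols).
#' @export
seed_list <- function(genes, label = "seed") {
  genes <- sort(normalize_symbols(genes))
  if (length(genes) == 0L) stop("seed list is empty after normalization")
  structure(list(label = label, genes = genes), class = "seed_list")
}

#' @export
print.seed_list <- function(x, ...) {
  cat("<seed_list>", x$label, "-", length(x$genes), "genes\n")
  invisible(x)
}

#' All genes appearing in a collection
#'
#' @param collection A `gene_set_collection`.
#' @return Sorted character vector of the union of all member sets.
#' @export
collection_universe <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  sort(unique(unlist(lapply(collection$sets, `[[`, "members"),
                     use.names = FALSE)))
}
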